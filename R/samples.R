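#' Construct a per-family analysis sample
#'
#' A `family_sample` holds the genotyped members of one family that have an
#' observed phenotype, ordered by phenotype category (category 1 first, the
#' reference category K last), together with their genotype proportions and
#' relatedness matrices.  Families whose retained members all fall in a
#' single category are kept but flagged non-informative; their score
#' contribution is exactly zero.
#'
#' @param Y integer phenotype categories in `1..K`.
#' @param X1,X2 allele proportions in \{0, 1/2, 1\} at locus 1 / locus 2
#'   (either may be `NULL` when the design does not use that locus).
#' @param phi kinship matrix for the members in `Y` (in the same order as
#'   supplied, before category sorting).
#' @param pi1,pi2 optional IBD sharing proportion matrices at locus 1 /
#'   locus 2; when absent, twice the kinship is substituted where needed.
#' @param K number of phenotype categories (>= 2).
#' @param ids member ids; `family` a family id.
#' @return An object of class `family_sample`.
#' @export
family_sample <- function(Y, X1 = NULL, X2 = NULL, phi, pi1 = NULL,
                          pi2 = NULL, K = max(Y), ids = NULL,
                          family = "1") {
  if (K < 2) stop("K must be >= 2")
  Y <- as.integer(Y)
  n <- length(Y)
  if (n > 0L && (min(Y) < 1L || max(Y) > K))
    stop("phenotype categories must lie in 1..K")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(Y)
  resort <- function(m) if (is.null(m)) NULL else m[ord, ord, drop = FALSE]
  fs <- list(
    family = family,
    ids = ids[ord],
    Y = Y[ord],
    X1 = if (is.null(X1)) NULL else as.numeric(X1)[ord],
    X2 = if (is.null(X2)) NULL else as.numeric(X2)[ord],
    n = n,
    nk = tabulate(Y, nbins = K),
    K = K,
    phi = resort(phi),
    pi1 = resort(pi1),
    pi2 = resort(pi2)
  )
  fs$informative <- length(unique(fs$Y)) >= 2L
  class(fs) <- "family_sample"
  fs
}

#' @export
print.family_sample <- function(x, ...) {
  cat("<family_sample> family ", x$family, ": n = ", x$n,
      ", categories (", paste(x$nk, collapse = ", "), ")",
      if (!x$informative) " [non-informative]", "\n", sep = "")
  invisible(x)
}

#' Proportion of a counted allele in two-allele genotypes
#'
#' Codes each genotype row as the proportion of the counted allele it
#' carries: 0, 1/2 or 1, with `NA` for missing genotypes.
#'
#' @param geno two-column allele matrix as stored by [read_pedigree()].
#' @param counted the counted allele.
#' @return Numeric vector of allele proportions.
#' @export
allele_proportion <- function(geno, counted) {
  miss <- is.na(geno[, 1L]) | is.na(geno[, 2L])
  p <- ((geno[, 1L] == counted) + (geno[, 2L] == counted)) / 2
  p[miss] <- NA_real_
  p
}

# minor allele among founders (fallback: all members)
founder_minor_allele <- function(ped_data, marker) {
  g <- ped_data$markers[[marker]]
  fdr <- is.na(ped_data$pedigree$father)
  al <- c(g[fdr, 1L], g[fdr, 2L])
  al <- al[!is.na(al)]
  if (!length(al)) {
    al <- c(g[, 1L], g[, 2L]); al <- al[!is.na(al)]
  }
  if (!length(al)) stop("marker ", marker, " has no observed alleles")
  tab <- sort(table(al))
  names(tab)[1L]
}

#' Assemble per-family analysis samples from pedigree data
#'
#' Restricts each family to its genotyped members with an observed
#' phenotype, maps the phenotype(s) to categories `1..K`, codes genotypes
#' as proportions of the counted allele, and attaches kinship and
#' (optionally) IBD sharing matrices.
#'
#' With `trait_spec = list(Y = "name")` the phenotype is dichotomous
#' (K = 2; category 1 = affected, category 2 = unaffected reference).  With
#' `trait_spec = list(Y1 = "endo", Y2 = "disease")` the two affection
#' traits are crossed into K = 4 categories: (Y1=1, Y2=0) is category 1,
#' (Y1=0, Y2=1) category 2, (Y1=1, Y2=1) category 3 and (Y1=0, Y2=0) the
#' reference category 4.
#'
#' @param ped_data a `gdt_ped_data` from [read_pedigree()].
#' @param trait_spec a list naming the affection trait(s); see Details.
#' @param loci character vector naming the marker used as `X1` and/or
#'   `X2`, e.g. `c(X1 = "snpA", X2 = "snpB")`; either may be omitted.
#' @param counted named character vector of counted alleles per marker;
#'   defaults to the minor allele among founders.
#' @param kinship optional precomputed [compute_kinship()] result.
#' @param ibd optional named list (`X1`, `X2`) of [read_ibd()] results.
#' @return A list of [family_sample()] objects, one per family.
#' @export
build_family_samples <- function(ped_data, trait_spec, loci,
                                 counted = NULL, kinship = NULL,
                                 ibd = NULL) {
  stopifnot(inherits(ped_data, "gdt_ped_data"))
  loci <- loci[!is.na(loci)]
  if (!all(names(loci) %in% c("X1", "X2")))
    stop("loci must be named X1 and/or X2")
  for (m in loci)
    if (!m %in% names(ped_data$markers)) stop("unknown marker: ", m)
  if (is.null(kinship)) kinship <- compute_kinship(ped_data$pedigree)

  # phenotype categories
  if (!is.null(trait_spec$Y)) {
    K <- 2L
    y <- ped_data$traits[[trait_spec$Y]]
    if (is.null(y)) stop("unknown trait: ", trait_spec$Y)
    cat_all <- ifelse(is.na(y), NA_integer_, ifelse(y == 1L, 1L, 2L))
  } else if (!is.null(trait_spec$Y1) && !is.null(trait_spec$Y2)) {
    K <- 4L
    y1 <- ped_data$traits[[trait_spec$Y1]]
    y2 <- ped_data$traits[[trait_spec$Y2]]
    if (is.null(y1) || is.null(y2))
      stop("unknown trait in trait_spec")
    cat_all <- four_category(y1, y2)
  } else stop("trait_spec must contain Y (K=2) or Y1 and Y2 (K=4)")

  # genotype proportions
  xp <- list(X1 = NULL, X2 = NULL)
  for (nm in names(loci)) {
    m <- loci[[nm]]
    ca <- if (!is.null(counted) && m %in% names(counted)) counted[[m]]
          else founder_minor_allele(ped_data, m)
    xp[[nm]] <- allele_proportion(ped_data$markers[[m]], ca)
  }

  out <- list()
  for (f in unique(ped_data$pedigree$family)) {
    sel <- which(ped_data$pedigree$family == f)
    keep <- !is.na(cat_all[sel])
    for (nm in names(loci)) keep <- keep & !is.na(xp[[nm]][sel])
    sel <- sel[keep]
    ids <- ped_data$pedigree$id[sel]
    phi <- kinship[[f]][ids, ids, drop = FALSE]
    sub <- function(mat_list, nm) {
      if (is.null(ibd) || is.null(ibd[[nm]])) return(NULL)
      ibd[[nm]][[f]][ids, ids, drop = FALSE]
    }
    out[[f]] <- family_sample(
      Y = cat_all[sel],
      X1 = if (is.null(xp$X1)) NULL else xp$X1[sel],
      X2 = if (is.null(xp$X2)) NULL else xp$X2[sel],
      phi = phi, pi1 = sub(ibd, "X1"), pi2 = sub(ibd, "X2"),
      K = K, ids = ids, family = f
    )
  }
  out
}

# crossing of two dichotomous traits into four categories
four_category <- function(y1, y2) {
  ifelse(is.na(y1) | is.na(y2), NA_integer_,
         ifelse(y1 == 1L & y2 == 0L, 1L,
         ifelse(y1 == 0L & y2 == 1L, 2L,
         ifelse(y1 == 1L & y2 == 1L, 3L, 4L))))
}
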