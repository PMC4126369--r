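#' Pedigree objects
#'
#' A `gdt_pedigree` is a data frame with columns `family`, `id`, `father`,
#' `mother` and `sex`, one row per pedigree member.  Founders have `NA` in
#' both parent columns; non-founders must have both parents present in the
#' same family.  Ids are stored as character.
#'
#' @param family,id,father,mother character (or coercible) vectors of equal
#'   length; missing parents may be given as `NA`, `"0"` or `""`.
#' @param sex optional sex codes (1 = male, 2 = female, 0/NA = unknown);
#'   read and preserved but not used by any test.
#' @return A data frame of class `gdt_pedigree`.
#' @export
gdt_pedigree <- function(family, id, father, mother, sex = NULL) {
  norm_id <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
    x
  }
  ped <- data.frame(
    family = as.character(family),
    id = as.character(id),
    father = norm_id(father),
    mother = norm_id(mother),
    sex = if (is.null(sex)) NA_integer_ else as.integer(sex),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
  class(ped) <- c("gdt_pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  for (f in unique(ped$family)) {
    p <- ped[ped$family == f, , drop = FALSE]
    if (anyDuplicated(p$id))
      stop("duplicated member id in family ", f, ": ",
           p$id[duplicated(p$id)][1L])
    one_parent <- xor(is.na(p$father), is.na(p$mother))
    if (any(one_parent))
      stop("family ", f, ", member ", p$id[one_parent][1L],
           ": exactly one parent specified; founders need neither, ",
           "non-founders both")
    for (col in c("father", "mother")) {
      bad <- !is.na(p[[col]]) & !(p[[col]] %in% p$id)
      if (any(bad))
        stop("family ", f, ", member ", p$id[bad][1L], ": unknown ",
             col, " id '", p[[col]][bad][1L], "'")
    }
    # acyclicity via topological ordering
    if (is.null(pedigree_order(p)))
      stop("family ", f, ": pedigree contains a cycle")
  }
  invisible(ped)
}

# topological order (parents before children) for one family, or NULL if
# the parent graph is cyclic
pedigree_order <- function(p) {
  n <- nrow(p)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(p$father) | p$father %in% p$id[placed]) &
      (is.na(p$mother) | p$mother %in% p$id[placed])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) NULL else ord
}

#' Kinship coefficients from a pedigree
#'
#' Computes the kinship matrix phi for each family by the standard
#' recursion: founders are mutually unrelated with phi_ii = 1/2;
#' for a non-founder i, phi_ij = (phi_father(i),j + phi_mother(i),j) / 2 for
#' j not a descendant of i, and phi_ii = (1 + phi_father(i),mother(i)) / 2.
#' Twice the kinship coefficient equals the expected identity-by-descent
#' sharing proportion at any locus.
#'
#' @param ped a [gdt_pedigree()].
#' @return A named list of symmetric kinship matrices, one per family, with
#'   member ids as dimnames.
#' @export
compute_kinship <- function(ped) {
  out <- list()
  for (f in unique(ped$family)) {
    p <- ped[ped$family == f, , drop = FALSE]
    ord <- pedigree_order(p)
    if (is.null(ord)) stop("family ", f, ": pedigree contains a cycle")
    p <- p[ord, , drop = FALSE]
    n <- nrow(p)
    idx <- stats::setNames(seq_len(n), p$id)
    phi <- matrix(0, n, n, dimnames = list(p$id, p$id))
    for (i in seq_len(n)) {
      if (is.na(p$father[i])) {
        phi[i, i] <- 0.5
      } else {
        fa <- idx[[p$father[i]]]
        mo <- idx[[p$mother[i]]]
        phi[i, i] <- 0.5 * (1 + phi[fa, mo])
        if (i > 1L) {
          j <- seq_len(i - 1L)
          phi[i, j] <- phi[j, i] <- 0.5 * (phi[fa, j] + phi[mo, j])
        }
      }
    }
    # restore input order
    back <- match(ped$id[ped$family == f], p$id)
    out[[f]] <- phi[back, back, drop = FALSE]
  }
  out
}

#' The canonical simulated 16-member, 3-generation pedigree
#'
#' Two grandparents, four of their children each married to an unrelated
#' spouse (8 members in generation 2), and six grandchildren (two children
#' in each of three of the couples).  This guarantees multiple first-cousin
#' pairs (kinship 1/16), which the family ascertainment rule relies on.
#'
#' @param family family id for the returned pedigree.
#' @return A [gdt_pedigree()] with 16 members.
#' @export
canonical_pedigree <- function(family = "1") {
  gdt_pedigree(
    family = rep(family, 16L),
    id = as.character(1:16),
    father = c(NA, NA, "1", "1", "1", "1", NA, NA, NA, NA,
               "3", "3", "4", "4", "5", "5"),
    mother = c(NA, NA, "2", "2", "2", "2", NA, NA, NA, NA,
               "7", "7", "8", "8", "9", "9"),
    sex = c(1, 2, 1, 1, 1, 1, 2, 2, 2, 2, 1, 2, 1, 2, 1, 2)
  )
}

#' @export
print.gdt_pedigree <- function(x, ...) {
  fams <- unique(x$family)
  cat("<gdt_pedigree> ", nrow(x), " members in ", length(fams),
      " famil", if (length(fams) == 1L) "y" else "ies", "\n", sep = "")
  NextMethod()
}
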