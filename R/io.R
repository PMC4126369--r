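#' Read pedigree, phenotype and genotype data in Merlin/QTDT format
#'
#' Reads a whitespace-delimited pedigree file (`.ped`: family, id, father,
#' mother, sex, then data fields) together with its data-definition file
#' (`.dat`) giving the type and name of each data field: `A name` for an
#' affection trait (coded 1 = unaffected, 2 = affected, 0 or x = missing)
#' and `M name` for a marker (two allele tokens, 0 = missing).  Both
#' readers accept gzip-compressed files.
#'
#' @param ped_path path to the pedigree file.
#' @param dat_path path to the data-definition file.
#' @return An object of class `gdt_ped_data`: a list with components
#'   `pedigree` (a [gdt_pedigree()]), `traits` (data frame of 0/1/NA
#'   affection codes, one row per member), and `markers` (named list of
#'   two-column character allele matrices, `NA` = missing).
#' @export
read_pedigree <- function(ped_path, dat_path) {
  dat <- read.table(dat_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("type", "name"))
  if (!all(dat$type %in% c("A", "M")))
    stop("unsupported .dat field type(s): ",
         paste(setdiff(dat$type, c("A", "M")), collapse = ", "),
         " (only A and M are supported)")
  raw <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  ncol_expected <- 5L + sum(ifelse(dat$type == "M", 2L, 1L))
  if (ncol(raw) != ncol_expected)
    stop("pedigree file has ", ncol(raw), " columns but the .dat file ",
         "implies ", ncol_expected,
         " (odd allele token count or trait/marker mismatch)")
  ped <- gdt_pedigree(raw[[1L]], raw[[2L]], raw[[3L]], raw[[4L]],
                      suppressWarnings(as.integer(raw[[5L]])))
  col <- 6L
  traits <- data.frame(row.names = seq_len(nrow(raw)))
  markers <- list()
  for (k in seq_len(nrow(dat))) {
    if (dat$type[k] == "A") {
      v <- raw[[col]]
      y <- ifelse(v == "2", 1L, ifelse(v == "1", 0L, NA_integer_))
      bad <- !(v %in% c("0", "1", "2", "x", "X"))
      if (any(bad))
        stop("invalid affection code '", v[bad][1L], "' for trait ",
             dat$name[k])
      traits[[dat$name[k]]] <- y
      col <- col + 1L
    } else {
      a1 <- raw[[col]]; a2 <- raw[[col + 1L]]
      a1[a1 == "0"] <- NA_character_
      a2[a2 == "0"] <- NA_character_
      markers[[dat$name[k]]] <- cbind(a1, a2)
      col <- col + 2L
    }
  }
  structure(list(pedigree = ped, traits = traits, markers = markers),
            class = "gdt_ped_data")
}

#' @export
print.gdt_ped_data <- function(x, ...) {
  cat("<gdt_ped_data> ", nrow(x$pedigree), " members, ",
      length(unique(x$pedigree$family)), " families, ",
      ncol(x$traits), " affection trait(s), ",
      length(x$markers), " marker(s)\n", sep = "")
  invisible(x)
}

#' Write pedigree data in Merlin/QTDT format
#'
#' Inverse of [read_pedigree()]; writing then reading reproduces the input
#' structures exactly.
#'
#' @param x a `gdt_ped_data` object.
#' @param ped_path,dat_path output paths.
#' @param map_path optional path for a `.map` file (chromosome, marker,
#'   position); markers are placed at 1 cM intervals on chromosome 1
#'   unless `map` is supplied.
#' @param map optional data frame with columns `chr`, `marker`, `pos`.
#' @return Invisibly, `x`.
#' @export
write_pedigree <- function(x, ped_path, dat_path, map_path = NULL,
                           map = NULL) {
  stopifnot(inherits(x, "gdt_ped_data"))
  dat <- rbind(
    if (ncol(x$traits)) data.frame(type = "A", name = names(x$traits)),
    if (length(x$markers)) data.frame(type = "M", name = names(x$markers))
  )
  write.table(dat, dat_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  out <- data.frame(
    family = x$pedigree$family, id = x$pedigree$id,
    father = ifelse(is.na(x$pedigree$father), "0", x$pedigree$father),
    mother = ifelse(is.na(x$pedigree$mother), "0", x$pedigree$mother),
    sex = ifelse(is.na(x$pedigree$sex), 0L, x$pedigree$sex),
    stringsAsFactors = FALSE
  )
  for (tr in names(x$traits)) {
    y <- x$traits[[tr]]
    out[[paste0("t_", tr)]] <- ifelse(is.na(y), "0", ifelse(y == 1L, "2", "1"))
  }
  for (m in names(x$markers)) {
    g <- x$markers[[m]]
    out[[paste0("m1_", m)]] <- ifelse(is.na(g[, 1L]), "0", g[, 1L])
    out[[paste0("m2_", m)]] <- ifelse(is.na(g[, 2L]), "0", g[, 2L])
  }
  write.table(out, ped_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  if (!is.null(map_path)) {
    if (is.null(map))
      map <- data.frame(chr = 1L, marker = names(x$markers),
                        pos = seq_along(x$markers))
    write.table(map, map_path, quote = FALSE, row.names = FALSE,
                col.names = c("CHROMOSOME", "MARKER", "POSITION"))
  }
  invisible(x)
}

#' Read per-marker IBD sharing proportions
#'
#' Reads a whitespace table in the Merlin `--ibd` column layout (family,
#' id1, id2, marker, P(IBD=0), P(IBD=1), P(IBD=2)) and converts each pair's
#' probabilities to the expected sharing proportion
#' pi = P(IBD=1)/2 + P(IBD=2).  Pairs absent from the file default to twice
#' the kinship coefficient, with a warning.
#'
#' @param path path to the IBD file (may be gzip-compressed).  A header
#'   line is detected and skipped automatically.
#' @param marker marker name to extract.
#' @param kinship per-family kinship matrices from [compute_kinship()],
#'   used both to define the member set and as the fallback for pairs
#'   missing from the file.
#' @return A named list of symmetric per-family matrices of IBD sharing
#'   proportions, diagonal 1.
#' @export
read_ibd <- function(path, marker, kinship) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*\\S+\\s+\\S+\\s+\\S+\\s+\\S+\\s+[0-9.eE+-]+\\s",
                       first) || grepl("FAMILY", toupper(first))
  tab <- read.table(path, header = FALSE, skip = as.integer(has_header),
                    stringsAsFactors = FALSE,
                    col.names = c("family", "id1", "id2", "marker",
                                  "p0", "p1", "p2"))
  tab <- tab[tab$marker == marker, , drop = FALSE]
  psum <- tab$p0 + tab$p1 + tab$p2
  if (any(abs(psum - 1) > 1e-6))
    stop("IBD probability row does not sum to 1 (family ",
         tab$family[abs(psum - 1) > 1e-6][1L], ")")
  out <- list()
  missing_pairs <- 0L
  for (f in names(kinship)) {
    phi <- kinship[[f]]
    ids <- rownames(phi)
    pim <- 2 * phi
    seen <- matrix(FALSE, nrow(phi), ncol(phi), dimnames = dimnames(phi))
    diag(seen) <- TRUE
    diag(pim) <- 1
    rows <- tab[as.character(tab$family) == f, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      i <- as.character(rows$id1[r]); j <- as.character(rows$id2[r])
      if (!(i %in% ids) || !(j %in% ids)) next
      v <- 0.5 * rows$p1[r] + rows$p2[r]
      pim[i, j] <- pim[j, i] <- v
      seen[i, j] <- seen[j, i] <- TRUE
      if (i == j) pim[i, j] <- v
    }
    missing_pairs <- missing_pairs + sum(!seen[upper.tri(seen)])
    out[[f]] <- pim
  }
  if (missing_pairs > 0L)
    warning(missing_pairs, " member pair(s) absent from IBD file for ",
            "marker ", marker, "; substituted 2*kinship")
  out
}

#' Read a Merlin/QTDT map file
#'
#' @param path path to a whitespace-delimited map file with columns
#'   chromosome, marker, position (header optional; gzip accepted).
#' @return Data frame with columns `chr`, `marker`, `pos`.
#' @export
read_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("CHROMOSOME|MARKER", toupper(first))
  tab <- read.table(path, header = FALSE, skip = as.integer(has_header),
                    stringsAsFactors = FALSE,
                    col.names = c("chr", "marker", "pos"))
  tab$pos <- as.numeric(tab$pos)
  tab
}
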