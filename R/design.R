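#' Model design specifications
#'
#' A `gdt_design` maps raw allele proportions (X1, X2) to per-category
#' predictor terms and assigns each term instance a coefficient label.
#' Labels repeated across categories share a coefficient (their score is
#' the sum of the per-category pair contrasts); labels used in a single
#' category give the simplified single-category contrast.  The reference
#' category K carries no terms.
#'
#' The built-in term vocabulary is `X1`, `X2`, `X1X2` (product) and
#' `X1(1-X2)`; [design_custom()] accepts additional term functions of the
#' same arity provided their locus content is declared.
#'
#' @name gdt_design
NULL

.term_funs <- list(
  "X1"       = function(x1, x2) x1,
  "X2"       = function(x1, x2) x2,
  "X1X2"     = function(x1, x2) x1 * x2,
  "X1(1-X2)" = function(x1, x2) x1 * (1 - x2)
)
.term_loci <- list(
  "X1" = 1L, "X2" = 2L, "X1X2" = c(1L, 2L), "X1(1-X2)" = c(1L, 2L)
)

new_design <- function(K, rows, term_funs = .term_funs,
                       term_loci = .term_loci, conditional_null = NULL,
                       name = "custom") {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  stopifnot(all(c("category", "term", "label") %in% names(rows)))
  if (K < 2) stop("K must be >= 2")
  if (any(rows$category >= K | rows$category < 1))
    stop("term categories must lie in 1..K-1 (reference category K has ",
         "no terms)")
  if (!all(rows$term %in% names(term_funs)))
    stop("unknown term(s): ",
         paste(setdiff(rows$term, names(term_funs)), collapse = ", "))
  if (!all(rows$term %in% names(term_loci)))
    stop("term(s) without declared loci: ",
         paste(setdiff(rows$term, names(term_loci)), collapse = ", "))
  labs <- unique(rows$label)
  shared <- vapply(labs, function(l)
    length(unique(rows$category[rows$label == l])) > 1L, logical(1L))
  structure(list(
    K = as.integer(K),
    rows = rows,
    term_funs = term_funs,
    term_loci = term_loci,
    labels = labs,
    shared = stats::setNames(shared, labs),
    loci_used = sort(unique(unlist(term_loci[unique(rows$term)]))),
    conditional_null = conditional_null,
    name = name
  ), class = "gdt_design")
}

#' @export
print.gdt_design <- function(x, ...) {
  cat("<gdt_design> '", x$name, "': K = ", x$K, ", ",
      length(x$labels), " coefficient label(s), ",
      x$K - 1L, " intercept(s)\n", sep = "")
  for (k in seq_len(x$K - 1L)) {
    r <- x$rows[x$rows$category == k, , drop = FALSE]
    cat("  category ", k, ": ",
        if (nrow(r)) paste0(r$term, " -> ", r$label, collapse = ", ")
        else "(no terms)", "\n", sep = "")
  }
  if (!is.null(x$conditional_null))
    cat("  conditional null labels: ",
        paste(x$conditional_null, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Full two-locus polytomous design (K = 4)
#'
#' Each non-reference category k gets terms X1, X2 and X1X2 with distinct
#' labels `b<k>1`, `b<k>2`, `b<k>3`: nine slope coefficients plus three
#' intercepts, i.e. three contrasts with four coefficients each.
#' The recorded conditional-null label set \{b12, b13, b22, b23, b32,
#' b33\} is the 6 d.f. test of locus 2 given locus 1 ("cpoly").
#'
#' @param K number of categories; must be 4.
#' @return A `gdt_design`.
#' @export
design_full_two_locus <- function(K = 4L) {
  if (K != 4L) stop("the full two-locus design is defined for K = 4")
  rows <- do.call(rbind, lapply(1:3, function(k)
    data.frame(category = k, term = c("X1", "X2", "X1X2"),
               label = paste0("b", k, 1:3))))
  new_design(4L, rows,
             conditional_null = c("b12", "b13", "b22", "b23", "b32", "b33"),
             name = "full2locus")
}

#' One-locus polytomous design
#'
#' Each non-reference category k gets the single term X2 with its own
#' label `bt<k>` (the full two-locus model restricted to X2 only);
#' `bt3` is the category-3 coefficient, tested alone as "b3(1L)".
#'
#' @param K number of categories (>= 2).
#' @return A `gdt_design`.
#' @export
design_one_locus <- function(K = 4L) {
  rows <- data.frame(category = seq_len(K - 1L), term = "X2",
                     label = paste0("bt", seq_len(K - 1L)))
  new_design(K, rows, conditional_null = NULL, name = "onelocus")
}

#' Endophenotype-to-disease design (K = 4)
#'
#' Locus 1 increases susceptibility to the endophenotype impairment and
#' possibly the disease; locus 2 increases disease susceptibility in
#' carriers of the locus-1 allele.  Category 1 gets X1 -> b11 and
#' X1(1-X2) -> be; category 2 gets X1 -> b21; category 3 gets X1 -> b31
#' and X1X2 -> b33.  The conditional-null label set is \{be, b33\} (the
#' 2 d.f. test of locus 2 given locus 1 under this model).
#'
#' @return A `gdt_design`.
#' @export
design_endo_to_disease <- function() {
  rows <- data.frame(
    category = c(1L, 1L, 2L, 3L, 3L),
    term = c("X1", "X1(1-X2)", "X1", "X1", "X1X2"),
    label = c("b11", "be", "b21", "b31", "b33")
  )
  new_design(4L, rows, conditional_null = c("be", "b33"),
             name = "endo2disease")
}

#' Dichotomous two-locus logistic design (K = 2)
#'
#' The usual two-locus logistic model for a dichotomous trait: category 1
#' gets X1 -> eta1, X2 -> eta2 and X1X2 -> eta3.  The conditional-null
#' label set \{eta2, eta3\} is the 2 d.f. test of locus 2 given locus 1
#' ("cdisease"/"cendo" depending on the phenotype tested).
#'
#' @return A `gdt_design`.
#' @export
design_dichotomous_two_locus <- function() {
  rows <- data.frame(category = 1L, term = c("X1", "X2", "X1X2"),
                     label = c("eta1", "eta2", "eta3"))
  new_design(2L, rows, conditional_null = c("eta2", "eta3"),
             name = "dichot2locus")
}

#' Custom design
#'
#' @param K number of categories.
#' @param rows data frame with columns `category`, `term`, `label`.
#' @param term_funs optional named list of additional term functions of
#'   `(x1, x2)`; merged with the built-in vocabulary.
#' @param term_loci named list giving, for each additional term, the loci
#'   (subset of `c(1, 2)`) its value depends on.
#' @param conditional_null optional label subset recorded as the design's
#'   conditional null hypothesis.
#' @param name design name used in printing and result rows.
#' @return A `gdt_design`.
#' @export
design_custom <- function(K, rows, term_funs = NULL, term_loci = NULL,
                          conditional_null = NULL, name = "custom") {
  tf <- .term_funs; tl <- .term_loci
  if (!is.null(term_funs)) tf[names(term_funs)] <- term_funs
  if (!is.null(term_loci)) tl[names(term_loci)] <- term_loci
  bad_loci <- !vapply(tl, function(l) all(l %in% c(1L, 2L)), logical(1L))
  if (any(bad_loci))
    stop("term loci must be a subset of c(1, 2): ",
         paste(names(tl)[bad_loci], collapse = ", "))
  d <- new_design(K, rows, tf, tl, conditional_null, name)
  empty <- setdiff(seq_len(K - 1L), unique(d$rows$category))
  if (length(empty))
    stop("non-reference category without terms: ",
         paste(empty, collapse = ", "))
  d
}

#' Evaluate design terms for one family
#'
#' Returns the matrix of evaluated term values, one column per design row
#' (a term instance in one category), for the members of a family sample.
#'
#' @param design a `gdt_design`.
#' @param fs a [family_sample()].
#' @return Numeric matrix `n x nrow(design$rows)`.
#' @export
evaluate_terms <- function(design, fs) {
  need1 <- 1L %in% design$loci_used
  need2 <- 2L %in% design$loci_used
  if (need1 && is.null(fs$X1)) stop("design requires X1 but sample has none")
  if (need2 && is.null(fs$X2)) stop("design requires X2 but sample has none")
  x1 <- if (is.null(fs$X1)) rep(NA_real_, fs$n) else fs$X1
  x2 <- if (is.null(fs$X2)) rep(NA_real_, fs$n) else fs$X2
  terms <- design$rows$term
  M <- matrix(0, fs$n, length(terms))
  for (r in seq_along(terms))
    M[, r] <- design$term_funs[[terms[r]]](x1, x2)
  M
}
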