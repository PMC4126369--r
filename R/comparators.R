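# derive a dichotomous family sample from a four-category one:
# "Y2" = disease status, "Y1" = endophenotype status,
# "Y2|Y1=1" = disease status among endophenotype-impaired members only
binary_sample <- function(fs, which = c("Y2", "Y1", "Y2|Y1=1")) {
  which <- match.arg(which)
  stopifnot(fs$K == 4L)
  keep <- switch(which,
    "Y2" = rep(TRUE, fs$n),
    "Y1" = rep(TRUE, fs$n),
    "Y2|Y1=1" = fs$Y %in% c(1L, 3L)
  )
  case <- switch(which,
    "Y2" = fs$Y %in% c(2L, 3L),
    "Y1" = fs$Y %in% c(1L, 3L),
    "Y2|Y1=1" = fs$Y == 3L
  )
  idx <- which(keep)
  sub <- function(m) if (is.null(m)) NULL else m[idx, idx, drop = FALSE]
  family_sample(
    Y = ifelse(case[idx], 1L, 2L),
    X1 = if (is.null(fs$X1)) NULL else fs$X1[idx],
    X2 = if (is.null(fs$X2)) NULL else fs$X2[idx],
    phi = sub(fs$phi), pi1 = sub(fs$pi1), pi2 = sub(fs$pi2),
    K = 2L, ids = fs$ids[idx], family = fs$family
  )
}

#' Dichotomous GDT variants and two-locus comparator tests
#'
#' Reference tests for a four-category (disease x endophenotype) sample,
#' all computed with the same within-family score machinery as
#' [gdt_test()]:
#' \describe{
#'   \item{GDT}{standard dichotomous GDT of the tested marker (X2) on the
#'     disease status Y2 (categories 2 and 3 vs 1 and 4).}
#'   \item{GDTc}{GDT of Y2 restricted to members with endophenotype
#'     impairment Y1 = 1 (other members treated as phenotype-unknown);
#'     within-family variance components are re-estimated in the subset.}
#'   \item{GDTe}{GDT of the endophenotype status Y1.}
#'   \item{cdisease / cendo}{2 d.f. conditional score test of \{eta2,
#'     eta3\} in the dichotomous two-locus logistic model
#'     ([design_dichotomous_two_locus()]) applied to Y2 / Y1, pairs
#'     weighted through the nuisance fit of eta1.}
#' }
#'
#' @param samples list of K = 4 [family_sample()] objects.
#' @param variant one of `"GDT"`, `"GDTc"`, `"GDTe"`, `"cdisease"`,
#'   `"cendo"`.
#' @param null,weights,kernel passed to [gdt_test()]; `weights` applies to
#'   the conditional variants only (the GDT variants are unweighted).
#' @return A `gdt_test` object.
#' @export
gdt_variant_test <- function(samples,
                             variant = c("GDT", "GDTc", "GDTe",
                                         "cdisease", "cendo"),
                             null = c("assoc", "linkage-assoc"),
                             weights = "eq6",
                             kernel = "auto") {
  variant <- match.arg(variant)
  null <- match.arg(null)
  if (variant %in% c("GDT", "GDTc", "GDTe")) {
    which <- switch(variant, GDT = "Y2", GDTc = "Y2|Y1=1", GDTe = "Y1")
    bs <- lapply(samples, binary_sample, which = which)
    d <- design_one_locus(K = 2L)
    out <- gdt_test(bs, d, tested = "bt1", weights = "equal", null = null,
                    kernel = kernel)
  } else {
    which <- if (variant == "cdisease") "Y2" else "Y1"
    bs <- lapply(samples, binary_sample, which = which)
    d <- design_dichotomous_two_locus()
    out <- gdt_test(bs, d, tested = c("eta2", "eta3"), weights = weights,
                    null = null, kernel = kernel)
  }
  out$model <- variant
  out
}
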