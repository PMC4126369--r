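#' Pair weights for within-family score tests
#'
#' Computes the symmetric matrix of pair weights C_ij for one family.  With
#' u_ij = (X_i^(c) - X_j^(c))' (alpha_{Y_i} - alpha_{Y_j}) built from the
#' nuisance fit of the phenotype on the free predictors:
#' \itemize{
#'   \item `"eq6"`: C_ij = 2 / (N (1 + exp(u_ij))) — the weights obtained
#'     when the variability of the nuisance estimates is neglected;
#'   \item `"eq7"`: C_ij = 8 exp(u_ij) / (N (1 + exp(u_ij))^3) — the
#'     dichotomous-GDT covariate weights carried over to the polytomous
#'     case;
#'   \item `"equal"`: C_ij = 1/N.
#' }
#' The normalizer is N = n (the family's retained member count), so that
#' with all nuisance coefficients zero both weight definitions reduce
#' exactly to the 1/n scaling of the unweighted score.
#'
#' @param fs a [family_sample()].
#' @param mode `"equal"`, `"eq6"` or `"eq7"`.
#' @param alpha_fit a `gdt_polyfit` of the free-coefficient model
#'   (required unless `mode = "equal"`).
#' @return An `n x n` symmetric weight matrix.
#' @export
compute_weights <- function(fs, mode = c("equal", "eq6", "eq7"),
                            alpha_fit = NULL) {
  mode <- match.arg(mode)
  n <- fs$n
  N <- n
  if (mode == "equal" || n == 0L)
    return(matrix(1 / max(N, 1L), n, n))
  if (is.null(alpha_fit))
    stop("alpha_fit is required for weight mode ", mode)
  L <- cbind(alpha_linpred(alpha_fit, fs), 0)  # n x K, reference = 0
  P <- L[, fs$Y, drop = FALSE]                 # P[i, j] = L(i, Y_j)
  dP <- diag(P)
  u <- outer(dP, dP, "+") - (P + t(P))
  if (!all(is.finite(u))) stop("non-finite pair weight argument u")
  eu <- exp(u)
  C <- switch(mode,
    eq6 = 2 / (N * (1 + eu)),
    eq7 = 8 * eu / (N * (1 + eu)^3)
  )
  C
}

# per-category contrast vectors: sv[[a]] is the n-vector s with
# s_i = sum_{j notin E_a} C_ij for i in E_a and s_j = -sum_{i in E_a} C_ij
# otherwise; the family score for a term column x in category a is x's'
.svectors <- function(fs, C, categories) {
  out <- list()
  for (a in categories) {
    inA <- fs$Y == a
    s <- numeric(fs$n)
    if (any(inA) && any(!inA)) {
      s[inA] <- rowSums(C[inA, !inA, drop = FALSE])
      s[!inA] <- -rowSums(C[!inA, inA, drop = FALSE])
    }
    out[[as.character(a)]] <- s
  }
  out
}

#' Family score contributions
#'
#' Computes the contribution of one family to the score statistic for each
#' coefficient label of a design.  For a label attached to a single
#' category a the contribution is the weighted contrast
#' sum_\{i in E_a\} sum_\{j notin E_a\} C_ij (X_i^(h) - X_j^(h)); for a
#' label shared across categories it is the sum of the corresponding
#' per-category contrasts.  With equal weights 1/n this is the unweighted
#' score with its 1/n scaling.  Non-informative families (a single
#' represented category) contribute exactly zero.
#'
#' @param fs a [family_sample()].
#' @param design a `gdt_design`.
#' @param C pair-weight matrix from [compute_weights()] (default: equal
#'   weights).
#' @param M optional precomputed [evaluate_terms()] matrix.
#' @return Named numeric vector of per-label score contributions.
#' @export
family_score <- function(fs, design, C = compute_weights(fs), M = NULL) {
  S <- stats::setNames(numeric(length(design$labels)), design$labels)
  if (!fs$informative || fs$n == 0L) return(S)
  if (is.null(M)) M <- evaluate_terms(design, fs)
  sv <- .svectors(fs, C, unique(design$rows$category))
  lab_idx <- match(design$rows$label, design$labels)
  cat_chr <- as.character(design$rows$category)
  for (r in seq_len(nrow(design$rows)))
    S[lab_idx[r]] <- S[lab_idx[r]] + sum(M[, r] * sv[[cat_chr[r]]])
  S
}

#' Pooled within-family variance of design term columns
#'
#' Estimates the term variances and covariances sigma_gh entering the
#' model-based variance kernels.  Because relatives' genotypes are
#' correlated, the plain within-family sum of squares is a biased
#' estimate of the genotype variance: under the kernel model
#' Cov(m_i, m_k) = P_ik sigma, the expectation of
#' sum_i (m_i - mbar)^2 is sigma * (tr(P) - 1'P1/n).  The estimator
#' therefore pools numerators sum_f sum_i (m_fig - mbar_fg)(m_fih -
#' mbar_fh) over families and divides by the summed kernel-corrected
#' degrees of freedom, with the kernel (per-locus IBD sharing or
#' 2*kinship, or their elementwise product for interaction terms)
#' matching the one used in [family_cov_model()].  For unrelated members
#' the denominator reduces to the usual n - 1.
#'
#' @param samples list of [family_sample()] objects.
#' @param design a `gdt_design`.
#' @param null_mode `"assoc"` or `"linkage-assoc"`; selects the kernel.
#' @return Covariance matrix over design rows (term instances); entries
#'   for term pairs at disjoint loci are 0 (their kernel is zero).
#' @export
pooled_term_sigma <- function(samples, design,
                              null_mode = c("assoc", "linkage-assoc")) {
  null_mode <- match.arg(null_mode)
  R <- nrow(design$rows)
  acc <- matrix(0, R, R)
  dof <- matrix(0, R, R)
  loci <- design$term_loci[design$rows$term]
  for (fs in samples) {
    # only score-contributing families enter, so that adding a
    # non-informative family leaves every statistic unchanged
    if (fs$n < 1L || !fs$informative) next
    M <- evaluate_terms(design, fs)
    Mc <- sweep(M, 2L, colMeans(M))
    acc <- acc + crossprod(Mc)
    for (r in seq_len(R)) for (q in r:R) {
      Kmat <- .kernel_matrix(fs, loci[[r]], loci[[q]], null_mode,
                             warn_missing = FALSE)
      if (is.null(Kmat)) next
      d <- sum(diag(Kmat)) - sum(Kmat) / fs$n
      dof[r, q] <- dof[q, r] <- dof[r, q] + d
    }
  }
  sig <- matrix(0, R, R)
  pos <- dof > 1e-10
  sig[pos] <- acc[pos] / dof[pos]
  sig
}

# relatedness matrix for one locus: actual IBD sharing under the
# association-only null (linkage allowed), twice the kinship under the
# linkage + association null or when IBD is unavailable
.relatedness <- function(fs, locus, null_mode, warn_missing = TRUE) {
  pim <- if (locus == 1L) fs$pi1 else fs$pi2
  if (null_mode == "assoc" && !is.null(pim)) return(pim)
  if (null_mode == "assoc" && is.null(pim) && warn_missing)
    warning("no IBD matrix for locus ", locus, " in family ", fs$family,
            "; substituting 2*kinship", call. = FALSE)
  2 * fs$phi
}

# model-based covariance kernel matrix for a pair of term instances
.kernel_matrix <- function(fs, loci_g, loci_h, null_mode, warn_missing) {
  lg <- sort(loci_g); lh <- sort(loci_h)
  if (length(lg) == 1L && length(lh) == 1L) {
    if (lg != lh) return(NULL)  # unlinked main terms: zero kernel
    return(.relatedness(fs, lg, null_mode, warn_missing))
  }
  if (length(lg) == 2L && length(lh) == 2L) {
    return(.relatedness(fs, 1L, null_mode, warn_missing) *
             .relatedness(fs, 2L, null_mode, warn_missing))
  }
  shared <- if (length(lg) == 1L) lg else lh
  .relatedness(fs, shared, null_mode, warn_missing)
}

#' Model-based family covariance of score contributions
#'
#' Computes one family's contribution to the variance-covariance matrix of
#' the per-label scores using the grouped (O(n^2)) form of the
#' quadruple-sum IBD kernel: for labels g, h with contrast vectors s_g,
#' s_h, Cov = sigma_gh * s_g' Pi s_h, where Pi is the per-locus IBD (or
#' 2*kinship) matrix for main terms, the elementwise product Pi1*Pi2 for
#' two product terms, and the shared locus' matrix for a main term and a
#' product term; main terms at different (unlinked) loci have zero
#' covariance.
#'
#' @param fs a [family_sample()].
#' @param design a `gdt_design`.
#' @param C pair-weight matrix.
#' @param sigma pooled term covariance from [pooled_term_sigma()].
#' @param null_mode `"assoc"` (use IBD sharing; linkage allowed under the
#'   null) or `"linkage-assoc"` (use 2*kinship).
#' @param warn_missing warn when IBD is requested but unavailable.
#' @return Labels-by-labels covariance contribution matrix.
#' @export
family_cov_model <- function(fs, design, C = compute_weights(fs), sigma,
                             null_mode = c("assoc", "linkage-assoc"),
                             warn_missing = TRUE) {
  null_mode <- match.arg(null_mode)
  labs <- design$labels
  V <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  if (!fs$informative || fs$n == 0L) return(V)
  sv <- .svectors(fs, C, unique(design$rows$category))
  R <- nrow(design$rows)
  lab_idx <- match(design$rows$label, labs)
  cat_chr <- as.character(design$rows$category)
  loci <- design$term_loci[design$rows$term]
  for (r in seq_len(R)) for (q in seq_len(R)) {
    Kmat <- .kernel_matrix(fs, loci[[r]], loci[[q]], null_mode,
                           warn_missing)
    if (is.null(Kmat)) next
    contrib <- sigma[r, q] *
      drop(crossprod(sv[[cat_chr[r]]], Kmat %*% sv[[cat_chr[q]]]))
    V[lab_idx[r], lab_idx[q]] <- V[lab_idx[r], lab_idx[q]] + contrib
  }
  V
}

# rank-revealing pseudo-inverse for symmetric PSD matrices
.pinv_sym <- function(V, tol = 1e-8) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  thr <- tol * max(abs(e$values), 0)
  keep <- e$values > thr
  rank <- sum(keep)
  if (rank == 0L)
    return(list(inv = matrix(0, nrow(V), ncol(V)), rank = 0L))
  inv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  list(inv = inv, rank = rank)
}

#' Within-family score test for polytomous phenotypes
#'
#' The central test of the package.  Sums the per-family score
#' contributions for the tested coefficient labels, estimates their
#' variance-covariance matrix, and forms the joint chi-square statistic
#' T = S' v(S)^-1 S (pseudo-inverse and rank-based degrees of freedom when
#' v(S) is singular) together with per-label Z statistics
#' Z = S / sqrt(v(S)).
#'
#' When labels other than the tested set carry free coefficients, subject
#' pairs are weighted using the nuisance fit of the phenotype on the free
#' predictors ([compute_weights()], expressions `"eq6"` or `"eq7"`); when
#' all labels are tested there are no free predictors and equal weights
#' 1/n apply.
#'
#' Two variance kernels are available: `"model"` (grouped IBD-kernel
#' quadruple sums, [family_cov_model()]) and `"empirical"` (the sum of
#' outer products of family score vectors, consistent because each family
#' contribution has expectation zero under the null).  The default
#' `"auto"` uses the model kernel when the tested labels are main-effect
#' terms of a single locus or a single label, and the empirical kernel for
#' mixed multi-term joint tests.
#'
#' @param samples list of [family_sample()] objects.
#' @param design a `gdt_design`.
#' @param tested labels to test (default: the design's conditional-null
#'   label set if present, otherwise all labels).
#' @param weights `"equal"`, `"eq6"` or `"eq7"`; default `"eq6"` when free
#'   labels exist, `"equal"` otherwise.
#' @param null `"assoc"` (association-only null: linkage allowed, actual
#'   IBD sharing used, with a warned 2*kinship fallback) or
#'   `"linkage-assoc"` (no linkage under the null: 2*kinship).
#' @param kernel `"auto"`, `"model"` or `"empirical"`.
#' @param alpha_fit optional precomputed nuisance fit (reused across
#'   markers in scans).
#' @return Object of class `gdt_test`.
#' @export
gdt_test <- function(samples, design, tested = NULL,
                     weights = NULL,
                     null = c("assoc", "linkage-assoc"),
                     kernel = c("auto", "model", "empirical"),
                     alpha_fit = NULL) {
  null <- match.arg(null)
  kernel <- match.arg(kernel)
  if (is.null(tested))
    tested <- if (!is.null(design$conditional_null)) design$conditional_null
              else design$labels
  bad <- setdiff(tested, design$labels)
  if (length(bad)) stop("unknown tested label(s): ",
                        paste(bad, collapse = ", "))
  free <- setdiff(design$labels, tested)
  if (is.null(weights)) weights <- if (length(free)) "eq6" else "equal"
  weights <- match.arg(weights, c("equal", "eq6", "eq7"))

  if (weights != "equal" && is.null(alpha_fit))
    alpha_fit <- fit_polytomous(samples, restrict_design(design, free))

  tested_rows <- design$rows[design$rows$label %in% tested, , drop = FALSE]
  tdesign <- new_design(design$K, tested_rows, design$term_funs,
                        design$term_loci, NULL, design$name)
  if (kernel == "auto") {
    # single-label tests use the IBD-kernel variance; joint tests
    # spanning several labels default to the empirical kernel, which is
    # consistent under both nulls (E[S_f] = 0) and robust to
    # between-family heterogeneity of the marker variance
    kernel <- if (length(tested) == 1L) "model" else "empirical"
  }

  sigma <- if (kernel == "model") pooled_term_sigma(samples, tdesign, null)
           else NULL
  S <- stats::setNames(numeric(length(tested)), tdesign$labels)
  Sf <- matrix(0, length(samples), length(tested),
               dimnames = list(NULL, tdesign$labels))
  V <- matrix(0, length(tested), length(tested),
              dimnames = list(tdesign$labels, tdesign$labels))
  warned <- FALSE
  n_informative <- 0L
  for (i in seq_along(samples)) {
    fs <- samples[[i]]
    C <- compute_weights(fs, weights, alpha_fit)
    M <- evaluate_terms(tdesign, fs)
    s <- family_score(fs, tdesign, C, M)
    Sf[i, ] <- s
    S <- S + s
    if (fs$informative) n_informative <- n_informative + 1L
    if (kernel == "model") {
      V <- V + withCallingHandlers(
        family_cov_model(fs, tdesign, C, sigma, null,
                         warn_missing = !warned),
        warning = function(w) {
          warned <<- TRUE
        })
    }
  }
  if (kernel == "empirical") {
    if (length(samples) < length(tested))
      warning("fewer families than tested labels; empirical covariance ",
              "is likely rank deficient")
    V <- crossprod(Sf)
  }
  neg <- diag(V) < -1e-10 * max(abs(diag(V)), 1)
  if (any(neg))
    stop("negative variance estimate for label(s) ",
         paste(tdesign$labels[neg], collapse = ", "),
         " (IBD/kinship inconsistency)")
  diag(V)[diag(V) < 0] <- 0

  untestable <- all(abs(V) == 0)
  if (untestable) {
    Tstat <- NA_real_; df <- 0L; p <- NA_real_
    Z <- S * NA_real_; pz <- Z
  } else {
    pv <- .pinv_sym(V)
    Tstat <- drop(S %*% pv$inv %*% S)
    df <- pv$rank
    p <- stats::pchisq(Tstat, df, lower.tail = FALSE)
    vd <- diag(V)
    Z <- ifelse(vd > 0, S / sqrt(vd), NA_real_)
    pz <- 2 * stats::pnorm(abs(Z), lower.tail = FALSE)
  }
  structure(list(
    S = S, vS = V, statistic = Tstat, df = df, p.value = p,
    Z = Z, p.single = pz,
    family_scores = Sf,
    tested = tested, free = free, weights = weights, null = null,
    kernel = kernel, K = design$K, model = design$name,
    n_families = length(samples), n_informative = n_informative,
    untestable = untestable
  ), class = "gdt_test")
}

#' @export
print.gdt_test <- function(x, ...) {
  cat("Within-family polytomous score test (", x$model, ")\n", sep = "")
  cat("tested: ", paste(x$tested, collapse = ", "),
      if (length(x$free)) paste0("  | free: ",
                                 paste(x$free, collapse = ", ")),
      "\n", sep = "")
  cat("weights: ", x$weights, ", null: ", x$null, ", kernel: ", x$kernel,
      ", informative families: ", x$n_informative, "/", x$n_families,
      "\n", sep = "")
  if (x$untestable) {
    cat("variance is identically zero: untestable\n")
    return(invisible(x))
  }
  if (length(x$tested) == 1L) {
    cat(sprintf("S = %.5g, Z = %.4f, p = %.4g\n",
                x$S, x$Z, x$p.single))
  } else {
    cat(sprintf("T = %.4f, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p.value))
  }
  invisible(x)
}

#' @export
summary.gdt_test <- function(object, ...) {
  tab <- data.frame(
    label = names(object$S),
    S = as.numeric(object$S),
    var = diag(object$vS),
    Z = as.numeric(object$Z),
    p = as.numeric(object$p.single)
  )
  out <- list(table = tab, statistic = object$statistic, df = object$df,
              p.value = object$p.value, test = object)
  class(out) <- "summary.gdt_test"
  out
}

#' @export
print.summary.gdt_test <- function(x, ...) {
  print(x$test)
  cat("\nPer-coefficient statistics:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.gdt_test <- function(object, ...) object$S

#' One-row summary of a test result
#'
#' @param x a `gdt_test`, `gdt_wald`, or list thereof.
#' @param marker,test optional identifiers included in the row.
#' @return A one-row data frame matching the scan TSV column layout.
#' @export
result_row <- function(x, marker = NA_character_, test = NA_character_) {
  if (inherits(x, "gdt_wald")) {
    return(data.frame(
      marker = marker, model = "geewald", test = test,
      S = if (x$df == 1L) unname(x$coef) else NA_real_,
      stat = x$statistic, df = x$df, p = x$p.value,
      null = NA_character_, weights = NA_character_,
      n_informative = x$n_families, stringsAsFactors = FALSE
    ))
  }
  single <- length(x$tested) == 1L
  data.frame(
    marker = marker, model = x$model, test = test,
    S = if (single) unname(x$S) else NA_real_,
    stat = if (single) unname(x$Z) else x$statistic,
    df = x$df,
    p = if (single) unname(x$p.single) else x$p.value,
    null = x$null, weights = x$weights,
    n_informative = x$n_informative, stringsAsFactors = FALSE
  )
}
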