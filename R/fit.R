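#' Restrict a design to a subset of coefficient labels
#'
#' Drops all term instances whose label is not in `labels`.  Used to build
#' the free-coefficient (nuisance) model for conditional tests.
#'
#' @param design a `gdt_design`.
#' @param labels labels to keep.
#' @return A `gdt_design` containing only the requested labels.
#' @export
restrict_design <- function(design, labels) {
  bad <- setdiff(labels, design$labels)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  rows <- design$rows[design$rows$label %in% labels, , drop = FALSE]
  new_design(design$K, rows, design$term_funs, design$term_loci,
             conditional_null = NULL,
             name = paste0(design$name, "[", paste(labels, collapse = ","),
                           "]"))
}

# stack family samples into pooled arrays for the multinomial fit:
# Y, per-category parameter-mapping matrices D[[k]] (n x p), family index
stack_samples <- function(samples, design) {
  K <- design$K
  p_int <- K - 1L
  labs <- design$labels
  p <- p_int + length(labs)
  par_names <- c(paste0("mu", seq_len(p_int)), labs)
  Ms <- lapply(samples, function(fs) evaluate_terms(design, fs))
  n_tot <- sum(vapply(samples, function(fs) fs$n, integer(1L)))
  Y <- integer(n_tot)
  fam <- character(n_tot)
  D <- lapply(seq_len(p_int), function(k) matrix(0, n_tot, p))
  at <- 0L
  for (s in seq_along(samples)) {
    fs <- samples[[s]]
    if (fs$n == 0L) next
    rows <- at + seq_len(fs$n)
    Y[rows] <- fs$Y
    fam[rows] <- fs$family
    for (k in seq_len(p_int)) {
      D[[k]][rows, k] <- 1
      sel <- which(design$rows$category == k)
      for (r in sel) {
        j <- p_int + match(design$rows$label[r], labs)
        D[[k]][rows, j] <- D[[k]][rows, j] + Ms[[s]][, r]
      }
    }
    at <- at + fs$n
  }
  list(Y = Y, D = D, fam = fam, p = p, K = K, par_names = par_names)
}

# category probabilities given eta (n x (K-1)); returns n x (K-1)
.multinom_probs <- function(eta) {
  ex <- exp(eta)
  ex / (1 + rowSums(ex))
}

#' Fit the pooled polytomous logistic model
#'
#' Maximum-likelihood fit of the multinomial logit model
#' log(P(Y=k)/P(Y=K)) = mu_k + terms_k implied by a design, pooling members
#' across families and ignoring the family structure (the independence
#' working correlation of a GEE, whose estimating equations coincide with
#' the pooled likelihood score).  Used to estimate the nuisance
#' coefficients that weight subject pairs in conditional score tests, and
#' as the point-estimate engine of the GEE Wald comparator.
#'
#' Damped Newton iterations with analytic gradient and Hessian;
#' convergence when the largest absolute score component is below 1e-8 or
#' the relative log-likelihood change is below 1e-10.  On apparent
#' separation (diverging coefficients or a singular Hessian) the fit is
#' restarted with a small ridge penalty (1e-6) and a warning.
#'
#' @param samples list of [family_sample()] objects.
#' @param design a `gdt_design` (already restricted to the free labels for
#'   nuisance use; see [restrict_design()]).
#' @return Object of class `gdt_polyfit` with components `mu` (intercepts),
#'   `coef` (named slope estimates, reference category fixed at 0),
#'   `theta`, `vcov_model`, `loglik`, `converged`, plus internals used by
#'   [gee_wald_test()].
#' @export
fit_polytomous <- function(samples, design) {
  st <- stack_samples(samples, design)
  K <- st$K
  counts <- tabulate(st$Y, nbins = K)
  if (any(counts == 0L))
    stop("empty phenotype category in pooled data: ",
         paste(which(counts == 0L), collapse = ", "))
  yk <- vapply(seq_len(K - 1L), function(k) as.numeric(st$Y == k),
               numeric(length(st$Y)))
  fit <- .newton_multinom(st, yk, ridge = 0)
  if (!fit$ok) {
    warning("polytomous fit unstable (possible separation); ",
            "refitting with ridge penalty 1e-6")
    fit <- .newton_multinom(st, yk, ridge = 1e-6)
  }
  theta <- stats::setNames(fit$theta, st$par_names)
  structure(list(
    mu = theta[seq_len(K - 1L)],
    coef = theta[-seq_len(K - 1L)],
    theta = theta,
    K = K,
    design = design,
    loglik = fit$loglik,
    converged = fit$converged,
    vcov_model = fit$vcov,
    .st = st, .yk = yk, .pk = fit$pk, .B = fit$B
  ), class = "gdt_polyfit")
}

.newton_multinom <- function(st, yk, ridge = 0, max_iter = 100L) {
  p <- st$p
  Km1 <- length(st$D)
  theta <- numeric(p)
  loglik <- function(th) {
    eta <- vapply(st$D, function(Dk) drop(Dk %*% th),
                  numeric(length(st$Y)))
    rs <- log1p(rowSums(exp(eta)))
    lp <- 0
    for (k in seq_len(Km1)) lp <- lp + sum(eta[, k] * yk[, k])
    lp - sum(rs) - 0.5 * ridge * sum(th^2)
  }
  ll <- loglik(theta)
  converged <- FALSE
  B <- NULL; pk <- NULL
  for (it in seq_len(max_iter)) {
    eta <- vapply(st$D, function(Dk) drop(Dk %*% theta),
                  numeric(length(st$Y)))
    pk <- .multinom_probs(eta)
    grad <- numeric(p)
    for (k in seq_len(Km1))
      grad <- grad + drop(crossprod(st$D[[k]], yk[, k] - pk[, k]))
    grad <- grad - ridge * theta
    B <- matrix(0, p, p)
    for (k in seq_len(Km1)) for (m in seq_len(Km1)) {
      w <- pk[, k] * ((k == m) - pk[, m])
      B <- B + crossprod(st$D[[k]], st$D[[m]] * w)
    }
    B <- B + ridge * diag(p)
    step <- tryCatch(solve(B, grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)))
      return(list(ok = FALSE, converged = FALSE, theta = theta,
                  loglik = ll, vcov = NULL, pk = pk, B = B))
    lam <- 1
    repeat {
      cand <- theta + lam * step
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    theta <- theta + lam * step
    ll_new <- loglik(theta)
    if (any(abs(theta) > 30))
      return(list(ok = FALSE, converged = FALSE, theta = theta,
                  loglik = ll_new, vcov = NULL, pk = pk, B = B))
    if (max(abs(grad)) < 1e-8 ||
        abs(ll_new - ll) < 1e-10 * (abs(ll) + 1e-10)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  # refresh B and pk at the solution
  eta <- vapply(st$D, function(Dk) drop(Dk %*% theta),
                numeric(length(st$Y)))
  pk <- .multinom_probs(eta)
  B <- matrix(0, p, p)
  for (k in seq_len(Km1)) for (m in seq_len(Km1)) {
    w <- pk[, k] * ((k == m) - pk[, m])
    B <- B + crossprod(st$D[[k]], st$D[[m]] * w)
  }
  B <- B + ridge * diag(p)
  vc <- tryCatch(solve(B), error = function(e) NULL)
  list(ok = TRUE, converged = converged, theta = theta, loglik = ll,
       vcov = vc, pk = pk, B = B)
}

#' @export
print.gdt_polyfit <- function(x, ...) {
  cat("<gdt_polyfit> K = ", x$K, ", logLik = ", format(x$loglik),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat("intercepts:\n"); print(x$mu)
  if (length(x$coef)) { cat("coefficients:\n"); print(x$coef) }
  invisible(x)
}

# slope-only linear predictors eta_k - mu_k for the members of one family
# under the fit's design; n x (K-1) matrix (reference category: 0)
alpha_linpred <- function(fit, fs) {
  M <- evaluate_terms(fit$design, fs)
  L <- matrix(0, fs$n, fit$K - 1L)
  for (r in seq_len(nrow(fit$design$rows))) {
    k <- fit$design$rows$category[r]
    L[, k] <- L[, k] + M[, r] * fit$coef[[fit$design$rows$label[r]]]
  }
  L
}

#' GEE-based Wald test of polytomous model coefficients
#'
#' Fits the pooled multinomial model by maximum likelihood (equivalently, a
#' GEE with independence working correlation) and tests the requested
#' coefficient labels with a Wald statistic using the family-clustered
#' sandwich variance B^-1 M B^-1, where B is the pooled information and M
#' the sum of outer products of per-family score vectors.  This comparator
#' uses between-family information and is not protected against population
#' stratification.
#'
#' @param samples list of [family_sample()] objects.
#' @param design a `gdt_design` (the full model).
#' @param labels coefficient labels to test jointly (default: all slope
#'   labels of the design).
#' @return Object of class `gdt_wald` with the estimates, sandwich
#'   variance, Wald chi-square statistic, df and p-value.
#' @export
gee_wald_test <- function(samples, design, labels = design$labels) {
  fit <- fit_polytomous(samples, design)
  if (!fit$converged) stop("pooled multinomial fit did not converge")
  st <- fit$.st
  # per-observation score contributions, then family totals
  U <- matrix(0, length(st$Y), st$p)
  for (k in seq_len(fit$K - 1L))
    U <- U + st$D[[k]] * (fit$.yk[, k] - fit$.pk[, k])
  G <- rowsum(U, st$fam)
  M <- crossprod(G)
  Binv <- solve(fit$.B)
  V <- Binv %*% M %*% Binv
  dimnames(V) <- list(st$par_names, st$par_names)
  idx <- match(labels, st$par_names)
  if (anyNA(idx)) stop("unknown label(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  est <- fit$theta[idx]
  Vs <- V[idx, idx, drop = FALSE]
  W <- drop(crossprod(est, solve(Vs, est)))
  df <- length(idx)
  structure(list(
    coef = est,
    vcov = Vs, vcov_all = V,
    statistic = W, df = df,
    p.value = stats::pchisq(W, df, lower.tail = FALSE),
    Z = if (df == 1L) est / sqrt(diag(Vs)) else est / sqrt(diag(Vs)),
    n_families = nrow(G),
    fit = fit,
    labels = labels
  ), class = "gdt_wald")
}

#' @export
print.gdt_wald <- function(x, ...) {
  cat("GEE Wald test (family-clustered sandwich variance)\n")
  cat("labels: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  cat(sprintf("Wald chi-square = %.4g, df = %d, p = %.4g (%d families)\n",
              x$statistic, x$df, x$p.value, x$n_families))
  invisible(x)
}
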