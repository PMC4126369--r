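d1 <- design_one_locus(2L)  # single term X2, label bt1

test_that("unweighted family score matches hand-computed contrasts", {
  fs <- family_sample(Y = c(1L, 2L, 2L, 2L), X2 = c(1, 0.5, 0, 0),
                      phi = diag(0.5, 4), K = 2L)
  expect_equal(unname(family_score(fs, d1)["bt1"]),
               (1 / 4) * ((1 - 0.5) + 1 + 1))  # 0.625
  # identical X for everyone: every pairwise difference vanishes
  fs0 <- family_sample(Y = c(1L, 1L, 2L), X2 = rep(0.5, 3),
                       phi = diag(0.5, 3), K = 2L)
  expect_equal(unname(family_score(fs0, d1)["bt1"]), 0)
})

test_that("K=2 equal-weight score equals the two-loop GDT oracle", {
  set.seed(21)
  for (r in 1:25) {
    fs <- random_family(sample(3:9, 1), K = 2L)
    expect_equal(unname(family_score(fs, d1)["bt1"]),
                 oracle_gdt_family_score(fs$X2, fs$Y == 1L))
  }
})

test_that("pair weights reduce to 1/N at alpha = 0 and match hand-computed
           values", {
  fs <- family_sample(Y = c(1L, 2L, 2L), X1 = c(1, 0, 1),
                      X2 = c(0, 1, 0.5), phi = diag(0.5, 3), K = 2L)
  free <- restrict_design(design_dichotomous_two_locus(), "eta1")
  afit0 <- structure(list(design = free, coef = c(eta1 = 0), K = 2L),
                     class = "gdt_polyfit")
  n <- fs$n
  expect_equal(compute_weights(fs, "eq6", afit0),
               matrix(1 / n, n, n))
  expect_equal(compute_weights(fs, "eq7", afit0),
               matrix(1 / n, n, n))
  expect_equal(compute_weights(fs, "equal"), matrix(1 / n, n, n))
  # X1 difference 1 between members 1 (Y=1) and 2 (Y=2), slope log 2
  afit <- structure(list(design = free, coef = c(eta1 = log(2)), K = 2L),
                    class = "gdt_polyfit")
  C6 <- compute_weights(fs, "eq6", afit)
  expect_equal(C6[1L, 2L], 2 / (3 * n))
  # u is symmetric, so C is too
  expect_equal(C6, t(C6))
  C7 <- compute_weights(fs, "eq7", afit)
  u <- log(2)
  expect_equal(C7[1L, 2L], 8 * exp(u) / (n * (1 + exp(u))^3))
})

test_that("weighted scores are linear in the weights and reduce to the
           unweighted form", {
  set.seed(31)
  fs <- random_family(6, K = 2L)
  C <- compute_weights(fs, "equal")
  expect_equal(family_score(fs, d1, C), family_score(fs, d1))
  expect_equal(family_score(fs, d1, 2 * C),
               2 * family_score(fs, d1, C))
  # hand-set weights on a 3-member family
  fs3 <- family_sample(Y = c(1L, 2L, 2L), X2 = c(1, 0, 0.5),
                       phi = diag(0.5, 3), K = 2L)
  C3 <- matrix(0, 3, 3)
  C3[1, 2] <- C3[2, 1] <- 0.2
  C3[1, 3] <- C3[3, 1] <- 0.4
  expect_equal(unname(family_score(fs3, d1, C3)["bt1"]),
               0.2 * (1 - 0) + 0.4 * (1 - 0.5))
})

test_that("model-based variance matches hand values and the quadruple-sum
           oracle", {
  # two unrelated members in different categories, equal weights 1/2
  fs <- family_sample(Y = c(1L, 2L), X2 = c(1, 0),
                      phi = diag(0.5, 2),
                      pi2 = diag(1, 2), K = 2L)
  sig <- pooled_term_sigma(list(fs), d1)
  V <- family_cov_model(fs, d1, compute_weights(fs), sig, "assoc")
  expect_equal(unname(V[1L, 1L]), sig[1L, 1L] / 2)
  # clonal family: all pi = 1 -> zero variance
  fsc <- family_sample(Y = c(1L, 2L), X2 = c(1, 0), phi = diag(0.5, 2),
                       pi2 = matrix(1, 2, 2), K = 2L)
  Vc <- family_cov_model(fsc, d1, compute_weights(fsc), sig, "assoc")
  expect_equal(unname(Vc[1L, 1L]), 0)
  # product-term kernel on two unrelated members
  dp <- design_custom(2L, data.frame(category = 1L, term = "X1X2",
                                     label = "g"))
  fsp <- family_sample(Y = c(1L, 2L), X1 = c(1, 0), X2 = c(1, 0),
                       phi = diag(0.5, 2), pi1 = diag(1, 2),
                       pi2 = diag(1, 2), K = 2L)
  sigp <- pooled_term_sigma(list(fsp), dp)
  Vp <- family_cov_model(fsp, dp, compute_weights(fsp), sigp, "assoc")
  expect_equal(unname(Vp[1L, 1L]), sigp[1L, 1L] / 2)

  # grouped fast path == naive O(n^4) oracle, random families and weights
  set.seed(41)
  for (r in 1:100) {
    fs <- random_family(sample(2:10, 1), K = 2L)
    C <- matrix(runif(fs$n^2), fs$n)
    C <- (C + t(C)) / 2
    sig <- pooled_term_sigma(list(fs), d1)
    V <- family_cov_model(fs, d1, C, sig, "assoc")
    Vq <- oracle_variance_quad(C, fs$Y == 1L, fs$pi2, sig[1L, 1L])
    expect_equal(unname(V[1L, 1L]), Vq, tolerance = 1e-10)
    # product-term kernel pi1 * pi2
    sigp <- pooled_term_sigma(list(fs), dp)
    Vp <- family_cov_model(fs, dp, C, sigp, "assoc")
    Vpq <- oracle_variance_quad(C, fs$Y == 1L, fs$pi1 * fs$pi2,
                                sigp[1L, 1L])
    expect_equal(unname(Vp[1L, 1L]), Vpq, tolerance = 1e-10)
  }
})

test_that("K=2 single-marker equal-weight test equals an independent
           dichotomous GDT implementation to 1e-10", {
  set.seed(51)
  fams <- lapply(1:100, function(i)
    random_family(sample(3:8, 1), K = 2L, family = as.character(i)))
  res <- gdt_test(fams, d1, tested = "bt1", weights = "equal",
                  null = "assoc", kernel = "model")
  oracle <- oracle_gdt_test(lapply(fams, function(f)
    list(x = f$X2, case = f$Y == 1L, P = f$pi2)))
  expect_equal(unname(res$S[["bt1"]]), oracle$S, tolerance = 1e-10)
  expect_equal(unname(res$vS[1L, 1L]), oracle$V, tolerance = 1e-10)
  expect_equal(unname(res$p.single[["bt1"]]), oracle$p, tolerance = 1e-10)
  # and with the kinship-based (linkage + association) null
  res2 <- gdt_test(fams, d1, tested = "bt1", weights = "equal",
                   null = "linkage-assoc", kernel = "model")
  oracle2 <- oracle_gdt_test(lapply(fams, function(f)
    list(x = f$X2, case = f$Y == 1L, P = 2 * f$phi)))
  expect_equal(unname(res2$vS[1L, 1L]), oracle2$V, tolerance = 1e-10)
})

test_that("joint statistic properties: zero score, chi1 = Z^2,
           reparameterization invariance, pseudo-inverse df", {
  set.seed(61)
  fams <- lapply(1:30, function(i) random_family(6, K = 4L))
  d <- design_one_locus(4L)
  res <- gdt_test(fams, d, weights = "equal", kernel = "model")
  expect_true(res$statistic >= 0)
  expect_equal(res$df, qr(res$vS)$rank)
  # scalar case: T = Z^2 and the chi-square p equals the normal p
  r1 <- gdt_test(fams, d, tested = "bt3", weights = "equal",
                 kernel = "model")
  expect_equal(r1$statistic, unname(r1$Z[["bt3"]])^2)
  expect_equal(r1$p.value, unname(r1$p.single[["bt3"]]))
  # invariance of T under invertible reparameterization
  S <- res$S; V <- res$vS
  A <- matrix(c(2, 1, 0, 0, 1, 3, 1, 0, 2), 3, 3)
  Tfun <- function(S, V) {
    e <- eigen((V + t(V)) / 2, symmetric = TRUE)
    keep <- e$values > 1e-8 * max(e$values)
    drop(crossprod(S, e$vectors[, keep] %*%
                        (crossprod(e$vectors[, keep], S) /
                           e$values[keep])))
  }
  expect_equal(Tfun(drop(A %*% S), A %*% V %*% t(A)), Tfun(S, V),
               tolerance = 1e-8)
  # degenerate: all scores zero -> T = 0, p = 1
  fs0 <- family_sample(Y = c(1L, 2L, 3L, 4L), X2 = rep(0.5, 4),
                       phi = diag(0.5, 4), K = 4L)
  r0 <- suppressWarnings(gdt_test(list(fs0, fs0), d, weights = "equal",
                                  kernel = "empirical"))
  expect_true(r0$untestable)
  expect_true(is.na(r0$p.value))
})

test_that("swapping the case and reference categories flips Z", {
  set.seed(71)
  fams <- lapply(1:20, function(i) random_family(5, K = 2L))
  swapped <- lapply(fams, function(f)
    family_sample(Y = 3L - f$Y, X2 = f$X2, phi = f$phi, pi2 = f$pi2,
                  K = 2L, ids = f$ids, family = f$family))
  r1 <- gdt_test(fams, d1, weights = "equal", kernel = "model")
  r2 <- gdt_test(swapped, d1, weights = "equal", kernel = "model")
  expect_equal(unname(r2$Z[["bt1"]]), -unname(r1$Z[["bt1"]]))
})

test_that("non-informative families change no statistic", {
  set.seed(81)
  fams <- lapply(1:20, function(i) random_family(5, K = 4L))
  extra <- family_sample(Y = rep(2L, 4), X2 = c(0, 0.5, 1, 0.5),
                         phi = diag(0.5, 4), K = 4L)
  d <- design_one_locus(4L)
  r1 <- gdt_test(fams, d, weights = "equal", kernel = "model")
  r2 <- gdt_test(c(fams, list(extra)), d, weights = "equal",
                 kernel = "model")
  expect_equal(r1$S, r2$S)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p.value, r2$p.value)
})

test_that("empirical and model-based variances agree on null families", {
  set.seed(91)
  # genotypes independent of phenotype: both kernels estimate the same
  # variance; compare diagonals on 800 families
  fams <- lapply(1:800, function(i)
    random_family(sample(4:8, 1), K = 4L, family = as.character(i)))
  d <- design_one_locus(4L)
  rm_ <- gdt_test(fams, d, weights = "equal", kernel = "model")
  re <- gdt_test(fams, d, weights = "equal", kernel = "empirical")
  expect_equal(diag(re$vS) / diag(rm_$vS), rep(1, 3),
               tolerance = 0.15, ignore_attr = TRUE)
})
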