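test_that("the canonical pedigree has the documented structure", {
  ped <- canonical_pedigree()
  expect_equal(nrow(ped), 16L)
  expect_equal(sum(is.na(ped$father)), 6L)  # 2 grandparents + 4 spouses
  phi <- compute_kinship(ped)[[1L]]
  # three generations: a grandparent-grandchild pair has phi = 1/8
  expect_true(any(abs(phi - 1 / 8) < 1e-12))
  # multiple first-cousin pairs
  expect_gte(sum(abs(phi[upper.tri(phi)] - 1 / 16) < 1e-12), 2L)
})

test_that("analytic prevalences reproduce the documented populations", {
  sc <- simulation_scenario()
  p0 <- analytic_prevalence(sc)
  expect_equal(round(p0[["disease"]], 4), 0.0076)
  expect_equal(round(p0[["endophenotype"]], 3), 0.128)
  scm <- simulation_scenario(mixture = TRUE)
  p1 <- analytic_prevalence(scm, population = 1)
  p2 <- analytic_prevalence(scm, population = 2)
  expect_equal(round(p1[["disease"]], 3), 0.005)
  expect_equal(round(p2[["disease"]], 3), 0.012)
  expect_equal(round(p1[["endophenotype"]], 3), 0.082)
  expect_equal(round(p2[["endophenotype"]], 3), 0.194)
  # no genotype effect: prevalences equal the intercept-only multinomial
  sc0 <- simulation_scenario(beta = cbind(example_coefficients()[, 1L],
                                          0, 0, 0))
  ex <- exp(example_coefficients()[, 1L])
  pk <- ex / (1 + sum(ex))
  p <- analytic_prevalence(sc0)
  expect_equal(p[["disease"]], unname(pk[2L] + pk[3L]))
  expect_equal(p[["endophenotype"]], unname(pk[1L] + pk[3L]))
})

test_that("gene dropping is Mendelian with exact realized IBD", {
  set.seed(171)
  trio <- gdt_pedigree("f", c("1", "2", "3"), c(NA, NA, "1"),
                       c(NA, NA, "2"))
  # child of two homozygous-reference parents is homozygous reference
  for (r in 1:200) {
    g <- simulate_genotypes(trio, raf = 0.3)
    if (g$dosage[1L] == 0 && g$dosage[2L] == 0)
      expect_equal(g$dosage[3L], 0)
    # parent-offspring realized sharing is always 1/2
    expect_equal(g$ibd[1L, 3L], 0.5)
    expect_equal(diag(g$ibd), rep(1, 3))
  }
})

test_that("founder allele frequency and sibling IBD match expectation", {
  set.seed(181)
  sc <- simulation_scenario(sigma2 = 0, alpha = 0)
  sim <- simulate_sample(sc, 1500, ascertained = FALSE)
  # founder dosage mean ~ RAF (members 1,2 are founders)
  fdr <- which(is.na(sim$pedigree$father))
  m <- mean(sim$X1[fdr, ])
  se <- sqrt(0.1 * 0.9 / (2 * length(fdr) * 1500))
  expect_lt(abs(m - 0.1), 3 * se)
  # full sibs (11, 12 in the canonical pedigree) share 1/2 on average
  i <- match("11", sim$pedigree$id); j <- match("12", sim$pedigree$id)
  sib_pi <- sim$pi2[i, j, ]
  expect_lt(abs(mean(sib_pi) - 0.5), 3 * sd(sib_pi) / sqrt(1500))
  # realized sharing averages 2*phi for cousin pairs too
  ci <- match("13", sim$pedigree$id)
  cpi <- sim$pi1[i, ci, ]
  expect_lt(abs(mean(cpi) - 0.125), 3 * sd(cpi) / sqrt(1500))
})

test_that("with no polygenic or familial effect the joint phenotype
           distribution is the polytomous model", {
  set.seed(191)
  sc <- simulation_scenario(sigma2 = 0, alpha = 0)
  sim <- simulate_sample(sc, 1200, ascertained = FALSE)
  cat4 <- gdtpoly:::four_category(as.integer(sim$Y1), as.integer(sim$Y2))
  x1 <- as.numeric(sim$X1); x2 <- as.numeric(sim$X2)
  # conditional category frequencies at the commonest genotype classes
  for (g1 in c(0, 0.5)) for (g2 in c(0, 0.5)) {
    sel <- x1 == g1 & x2 == g2
    m <- sum(sel)
    pk <- gdtpoly:::.category_probs(sc$beta, 0, g1, g2)
    for (k in 1:4) {
      ek <- m * pk[k]
      if (ek < 10) next
      ok <- sum(cat4[sel] == k)
      expect_lt(abs(ok - ek), 3 * sqrt(m * pk[k] * (1 - pk[k])) + 1e-9)
    }
  }
})

test_that("the ascertainment rule is exactly the affected-cousin-pair
           criterion", {
  ped <- canonical_pedigree()
  phi <- compute_kinship(ped)[[1L]]
  Y2 <- rep(0L, 16)
  expect_false(ascertain_family(Y2, phi))
  # two affected full siblings do not qualify
  Y2s <- rep(0L, 16); Y2s[match(c("11", "12"), ped$id)] <- 1L
  expect_false(ascertain_family(Y2s, phi))
  # affected members of two different sibships are first cousins
  Y2c <- rep(0L, 16); Y2c[match(c("11", "13"), ped$id)] <- 1L
  expect_true(ascertain_family(Y2c, phi))
  # every kept family passes the rule
  set.seed(201)
  sim <- simulate_sample(simulation_scenario(), 25)
  for (j in seq_len(sim$n_families))
    expect_true(ascertain_family(sim$Y2[, j], sim$phi))
  # ascertainment enriches for the disease
  prev <- analytic_prevalence(simulation_scenario())[["disease"]]
  expect_gt(mean(sim$Y2), prev)
})

test_that("simulation is deterministic given the seed", {
  sc <- simulation_scenario()
  set.seed(211); s1 <- simulate_sample(sc, 10)
  set.seed(211); s2 <- simulate_sample(sc, 10)
  expect_identical(s1$Y2, s2$Y2)
  expect_identical(s1$X2, s2$X2)
  expect_identical(s1$pi2, s2$pi2)
})

test_that("simulated samples round-trip through the Merlin/QTDT files", {
  set.seed(221)
  sim <- simulate_sample(simulation_scenario(), 8)
  d <- withr::local_tempdir()
  paths <- sim_write_files(sim, file.path(d, "sim"))
  pd <- read_pedigree(paths[1L], paths[2L])
  expect_equal(length(unique(pd$pedigree$family)), 8L)
  # dosages of the counted ("2") allele reproduce the simulated ones
  x2 <- allele_proportion(pd$markers$locus2, "2")
  expect_equal(matrix(x2, nrow = 16), unname(sim$X2))
  kin <- compute_kinship(pd$pedigree)
  pim <- read_ibd(paths[4L], "locus2", kin)
  for (j in 1:8)
    expect_equal(unname(pim[[as.character(j)]]), unname(sim$pi2[, , j]))
})
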