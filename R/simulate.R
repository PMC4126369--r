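#' Example polytomous coefficient table
#'
#' The default generating model for the simulator: a 3 x 4 matrix of
#' regression coefficients (rows: categories (Y1,Y2) = (1,0), (0,1), (1,1)
#' against the (0,0) reference; columns: intercept, X1, X2, X1X2).  The
#' default values give a disease population prevalence of 0.0076 and an
#' endophenotype impairment prevalence of 0.128 at risk allele frequencies
#' 0.1 (locus 1) and 0.3 (locus 2): locus 1 raises endophenotype risk
#' (odds ratio 2), and locus 2 raises disease-with-impairment risk only
#' through its interaction with locus 1 (odds ratio 16).
#'
#' @return A 3 x 4 numeric matrix.
#' @export
example_coefficients <- function() {
  matrix(c(-2,   log(2), 0, -log(2),
           -5.5, 0,      0,  0,
           -5.5, 0,      0,  log(16)),
         3L, 4L, byrow = TRUE,
         dimnames = list(c("endo", "disease", "both"),
                         c("intercept", "X1", "X2", "X1X2")))
}

#' Simulation scenario
#'
#' Bundles every parameter of the pedigree simulator: allele frequencies,
#' the polytomous coefficient table, the population-heterogeneity
#' intercept shift, the polygenic and familial-aggregation parameters of
#' the two-step phenotype model, the null-marker allele frequencies, and
#' the pedigree structure.
#'
#' @param raf1,raf2 risk allele frequencies at locus 1 / locus 2.
#' @param beta 3 x 4 coefficient matrix (see [example_coefficients()]).
#' @param mixture if `TRUE`, families are drawn with equal probability
#'   from two populations whose intercepts are shifted by `-shift` /
#'   `+shift` and whose null-marker allele frequencies are
#'   `null_maf[1]` / `null_maf[2]`.
#' @param shift intercept shift magnitude under heterogeneity.
#' @param null_maf allele frequency of the null (linkage-equilibrium)
#'   marker at locus 2; length 2 when `mixture = TRUE`.  Defaults to
#'   `raf2` (homogeneous) or `c(0.1, 0.5)` (mixture).
#' @param sigma2 polygenic variance on the logit scale of the disease.
#' @param alpha weight of relatives' endophenotype status on the disease
#'   logit (modulated by kinship).
#' @param nu centering constant in (0, 1) balancing the risk increase
#'   (1 - nu) of an impaired relative against the risk decrease (-nu) of
#'   an unimpaired one; default: the endophenotype population prevalence.
#' @param n_families default number of ascertained families per sample.
#' @param pedigree the family structure ([canonical_pedigree()] by
#'   default).
#' @return An object of class `gdt_scenario`.
#' @export
simulation_scenario <- function(raf1 = 0.1, raf2 = 0.3,
                                beta = example_coefficients(),
                                mixture = FALSE, shift = 0.5,
                                null_maf = NULL,
                                sigma2 = 1, alpha = 1, nu = 0.128,
                                n_families = 100L,
                                pedigree = canonical_pedigree()) {
  if (is.null(null_maf)) null_maf <- if (mixture) c(0.1, 0.5) else raf2
  stopifnot(raf1 > 0, raf1 < 1, raf2 > 0, raf2 < 1,
            all(null_maf > 0), all(null_maf < 1),
            nu > 0, nu < 1, sigma2 >= 0,
            is.matrix(beta), nrow(beta) == 3L, ncol(beta) == 4L)
  if (mixture && length(null_maf) != 2L)
    stop("mixture scenarios need null_maf of length 2")
  structure(list(raf1 = raf1, raf2 = raf2, beta = beta,
                 mixture = mixture, shift = shift, null_maf = null_maf,
                 sigma2 = sigma2, alpha = alpha, nu = nu,
                 n_families = as.integer(n_families),
                 pedigree = pedigree),
            class = "gdt_scenario")
}

#' @export
print.gdt_scenario <- function(x, ...) {
  cat("<gdt_scenario> RAFs (", x$raf1, ", ", x$raf2, "), ",
      if (x$mixture) paste0("two-population mixture (shift ", x$shift,
                            ", null MAF ",
                            paste(x$null_maf, collapse = "/"), ")")
      else "homogeneous population",
      ", sigma2 = ", x$sigma2, ", alpha = ", x$alpha, ", nu = ", x$nu,
      "\n", sep = "")
  invisible(x)
}

# category probabilities of the polytomous model at one genotype
.category_probs <- function(beta, shift, x1, x2) {
  eta <- beta[, 1L] + shift + beta[, 2L] * x1 + beta[, 3L] * x2 +
    beta[, 4L] * x1 * x2
  ex <- exp(eta)
  c(ex, 1) / (1 + sum(ex))  # categories (1,0),(0,1),(1,1),(0,0)
}

#' Analytic population prevalences
#'
#' Enumerates the nine two-locus genotype classes under Hardy-Weinberg
#' equilibrium at the scenario's allele frequencies, evaluates the
#' polytomous category probabilities at each (proportion-coded) genotype,
#' and averages.  The disease prevalence is P[(0,1)] + P[(1,1)]; the
#' endophenotype impairment prevalence is P[(1,0)] + P[(1,1)].
#'
#' @param scenario a [simulation_scenario()].
#' @param population `NULL` (no intercept shift), `1` or `2` (mixture
#'   population with intercepts shifted by `-shift` / `+shift`).
#' @return Named vector `c(disease = , endophenotype = )`.
#' @export
analytic_prevalence <- function(scenario, population = NULL) {
  shift <- 0
  if (!is.null(population)) {
    stopifnot(population %in% 1:2)
    shift <- if (population == 1) -scenario$shift else scenario$shift
  }
  g <- c(0, 0.5, 1)
  hw <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
  w1 <- hw(scenario$raf1); w2 <- hw(scenario$raf2)
  dis <- 0; endo <- 0
  for (i in 1:3) for (j in 1:3) {
    pk <- .category_probs(scenario$beta, shift, g[i], g[j])
    w <- w1[i] * w2[j]
    dis <- dis + w * (pk[2L] + pk[3L])
    endo <- endo + w * (pk[1L] + pk[3L])
  }
  c(disease = unname(dis), endophenotype = unname(endo))
}

# realized IBD sharing proportion matrix from founder-slot allele labels
ibd_from_labels <- function(la, lb) {
  n <- length(la)
  m1 <- outer(la, la, "==") + outer(lb, lb, "==")
  m2 <- outer(la, lb, "==") + outer(lb, la, "==")
  pim <- pmax(m1, m2) / 2
  diag(pim) <- 1
  pim
}

#' Gene-drop genotypes through one pedigree (reference implementation)
#'
#' Pure-R single-family gene dropping: founder alleles iid
#' Bernoulli(`raf`) under Hardy-Weinberg equilibrium, each child allele
#' drawn uniformly from the parent's two, founder-allele labels tracked so
#' realized IBD sharing is exact.  [simulate_sample()] uses a compiled
#' batch equivalent of this routine.
#'
#' @param pedigree a single-family [gdt_pedigree()].
#' @param raf risk allele frequency.
#' @return List with `dosage` (allele proportions in \{0, 1/2, 1\}), `ibd`
#'   (realized sharing proportion matrix) and the allele label/type
#'   internals.
#' @export
simulate_genotypes <- function(pedigree, raf) {
  ord <- pedigree_order(pedigree)
  p <- pedigree[ord, , drop = FALSE]
  n <- nrow(p)
  idx <- stats::setNames(seq_len(n), p$id)
  founders <- which(is.na(p$father))
  typ <- rbinom(2L * length(founders), 1L, raf)
  la <- lb <- integer(n)
  for (i in seq_len(n)) {
    if (is.na(p$father[i])) {
      f <- match(i, founders)
      la[i] <- 2L * f - 1L; lb[i] <- 2L * f
    } else {
      fa <- idx[[p$father[i]]]; mo <- idx[[p$mother[i]]]
      la[i] <- if (runif(1L) < 0.5) la[fa] else lb[fa]
      lb[i] <- if (runif(1L) < 0.5) la[mo] else lb[mo]
    }
  }
  back <- match(pedigree$id, p$id)
  la <- la[back]; lb <- lb[back]
  list(dosage = (typ[la] + typ[lb]) / 2,
       ibd = ibd_from_labels(la, lb),
       labels = cbind(la, lb), types = typ)
}

#' Two-step phenotype simulation (reference implementation)
#'
#' Given genotype proportions for one family, draws the endophenotype
#' Y1_i from its polytomous marginal P[(1,0)|X_i] + P[(1,1)|X_i], then the
#' disease Y2_i from a Bernoulli with logit gamma(X_i, Y1_i) + U_i +
#' alpha * sum_\{h != i\} (Y1_h - nu) phi_ih, where U ~ N(0, sigma^2 Phi)
#' is drawn once per family and gamma is the within-stratum log-odds of
#' disease implied by the polytomous model (so that with sigma^2 = 0 and
#' alpha = 0 the joint (Y1, Y2) distribution is exactly the polytomous
#' model).
#'
#' @param scenario a [simulation_scenario()].
#' @param X1,X2 genotype proportions for the family members.
#' @param phi kinship matrix of the family.
#' @param population mixture population (`NULL`, 1 or 2).
#' @return List with integer vectors `Y1` and `Y2`.
#' @export
simulate_phenotypes <- function(scenario, X1, X2, phi, population = NULL) {
  shift <- 0
  if (!is.null(population))
    shift <- if (population == 1) -scenario$shift else scenario$shift
  beta <- scenario$beta
  n <- length(X1)
  eta <- sapply(1:3, function(k)
    beta[k, 1L] + shift + beta[k, 2L] * X1 + beta[k, 3L] * X2 +
      beta[k, 4L] * X1 * X2)
  if (n == 1L) eta <- matrix(eta, 1L)
  den <- 1 + rowSums(exp(eta))
  pY1 <- (exp(eta[, 1L]) + exp(eta[, 3L])) / den
  Y1 <- rbinom(n, 1L, pY1)
  Sig <- scenario$sigma2 * phi
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("sigma^2 * Phi is not positive semidefinite")
  U <- if (scenario$sigma2 > 0) drop(t(chol(Sig)) %*% rnorm(n))
       else numeric(n)
  phi0 <- phi; diag(phi0) <- 0
  kin <- scenario$alpha * drop(phi0 %*% (Y1 - scenario$nu))
  g <- ifelse(Y1 == 1L, eta[, 3L] - eta[, 1L], eta[, 2L])
  Y2 <- rbinom(n, 1L, plogis(g + U + kin))
  list(Y1 = Y1, Y2 = Y2)
}

#' Family ascertainment rule
#'
#' Keep a family if and only if it contains at least one first-cousin pair
#' (kinship exactly 1/16) in which both members are affected by the
#' disease.
#'
#' @param Y2 disease status vector.
#' @param phi kinship matrix in the same member order.
#' @return `TRUE` to keep, `FALSE` to reject.
#' @export
ascertain_family <- function(Y2, phi) {
  cp <- which(abs(phi - 1 / 16) < 1e-12 & upper.tri(phi), arr.ind = TRUE)
  any(Y2[cp[, 1L]] == 1L & Y2[cp[, 2L]] == 1L)
}

#' Simulate a sample of ascertained families
#'
#' Rejection-samples families from the scenario's pedigree structure until
#' `n_families` satisfy the ascertainment rule (at least one affected
#' first-cousin pair), using the compiled batch gene-dropping engine.
#' Under a mixture scenario each family's population of origin is
#' Bernoulli(1/2), with the matching intercept shift and null-marker
#' allele frequency.  A null marker at locus 2 in linkage equilibrium with
#' the causal variant is generated by assigning independent founder allele
#' types on the same locus-2 segregation pattern, so it shares the locus-2
#' IBD pattern but carries no phenotype information.
#'
#' @param scenario a [simulation_scenario()].
#' @param n_families number of ascertained families to return.
#' @param ascertained if `FALSE`, keep every simulated family.
#' @return Object of class `gdt_sim`: matrices (members x families) `Y1`,
#'   `Y2`, `X1` (causal locus-1 proportions), `X2` (causal locus-2),
#'   `Xnull` (null marker), arrays `pi1`, `pi2` of realized IBD sharing,
#'   the population labels, kinship matrix, and the total number of
#'   families drawn.
#' @export
simulate_sample <- function(scenario, n_families = scenario$n_families,
                            ascertained = TRUE) {
  ped <- scenario$pedigree
  if (length(unique(ped$family)) != 1L)
    stop("the scenario pedigree must be a single family structure")
  ord <- pedigree_order(ped)
  p <- ped[ord, , drop = FALSE]
  n <- nrow(p)
  idx <- stats::setNames(seq_len(n), p$id)
  fa <- ifelse(is.na(p$father), -1L, idx[p$father] - 1L)
  mo <- ifelse(is.na(p$mother), -1L, idx[p$mother] - 1L)
  phi <- compute_kinship(ped)[[1L]][p$id, p$id]
  nF <- sum(is.na(p$father))
  Lchol <- if (scenario$sigma2 > 0) t(chol(scenario$sigma2 * phi))
           else matrix(0, n, n)
  phiAlpha <- scenario$alpha * phi; diag(phiAlpha) <- 0
  cp <- which(abs(phi - 1 / 16) < 1e-12 & upper.tri(phi), arr.ind = TRUE)
  if (ascertained && nrow(cp) == 0L)
    stop("pedigree has no first-cousin pairs; ascertainment impossible")
  cp <- matrix(as.integer(cp - 1L), ncol = 2L)

  # the two mixture populations are represented in equal proportions in
  # the final (ascertained) sample: half the families from each
  shifts <- if (scenario$mixture) c(-scenario$shift, scenario$shift)
            else 0
  targets <- if (scenario$mixture)
    c(n_families %/% 2L, n_families - n_families %/% 2L) else n_families
  acc <- list()
  pop <- integer(0)
  draws <- 0L
  for (s in seq_along(shifts)) {
    kept <- 0L
    batch <- 4000L
    rate <- NA_real_
    drawn_s <- 0L
    while (kept < targets[s]) {
      need <- targets[s] - kept
      if (!is.na(rate) && rate > 0)
        batch <- min(500000L,
                     as.integer(ceiling(need / rate * 1.4)) + 100L)
      res <- sim_batch_cpp(batch, fa, mo, scenario$raf1, scenario$raf2,
                           scenario$beta, shifts[s], Lchol, phiAlpha,
                           scenario$nu, cp, ascertained, need)
      draws <- draws + res$draws
      drawn_s <- drawn_s + res$draws
      if (res$kept > 0L) {
        acc[[length(acc) + 1L]] <- res
        pop <- c(pop, rep(s, res$kept))
        kept <- kept + res$kept
      }
      rate <- if (drawn_s > 0L) max(kept, 1L) / drawn_s else NA_real_
    }
  }
  cbindall <- function(nm) do.call(cbind, lapply(acc, `[[`, nm))
  Y1 <- cbindall("Y1"); Y2 <- cbindall("Y2")
  la1 <- cbindall("la1"); lb1 <- cbindall("lb1")
  la2 <- cbindall("la2"); lb2 <- cbindall("lb2")
  t1 <- cbindall("t1"); t2 <- cbindall("t2")
  Fam <- ncol(Y1)
  X1 <- X2 <- Xn <- matrix(0, n, Fam)
  pi1 <- pi2 <- array(0, c(n, n, Fam))
  for (j in seq_len(Fam)) {
    X1[, j] <- (t1[la1[, j] + 1L, j] + t1[lb1[, j] + 1L, j]) / 2
    X2[, j] <- (t2[la2[, j] + 1L, j] + t2[lb2[, j] + 1L, j]) / 2
    maf <- if (scenario$mixture) scenario$null_maf[pop[j]]
           else scenario$null_maf[1L]
    tn <- rbinom(2L * nF, 1L, maf)
    Xn[, j] <- (tn[la2[, j] + 1L] + tn[lb2[, j] + 1L]) / 2
    pi1[, , j] <- ibd_from_labels(la1[, j], lb1[, j])
    pi2[, , j] <- ibd_from_labels(la2[, j], lb2[, j])
  }
  rownames(Y1) <- rownames(Y2) <- rownames(X1) <- rownames(X2) <-
    rownames(Xn) <- p$id
  structure(list(
    pedigree = ped[ord, , drop = FALSE], phi = phi, pop = pop,
    Y1 = Y1, Y2 = Y2, X1 = X1, X2 = X2, Xnull = Xn,
    pi1 = pi1, pi2 = pi2,
    n_families = Fam, draws = draws, scenario = scenario
  ), class = "gdt_sim")
}

#' @export
print.gdt_sim <- function(x, ...) {
  cat("<gdt_sim> ", x$n_families, " families of ", nrow(x$Y1),
      " members (", x$draws, " drawn", ")\n", sep = "")
  invisible(x)
}

#' Convert a simulated sample to per-family analysis samples
#'
#' Builds K = 4 [family_sample()] objects with `X1` the causal locus-1
#' proportions and `X2` the requested tested marker, carrying the realized
#' per-locus IBD matrices (the null marker shares the locus-2 pattern).
#'
#' @param sim a `gdt_sim` from [simulate_sample()].
#' @param tested `"null"` (the linkage-equilibrium marker at locus 2) or
#'   `"causal"` (the causal locus-2 variant).
#' @return List of [family_sample()] objects.
#' @export
sim_to_samples <- function(sim, tested = c("null", "causal")) {
  tested <- match.arg(tested)
  Xt <- if (tested == "null") sim$Xnull else sim$X2
  lapply(seq_len(sim$n_families), function(j)
    family_sample(
      Y = four_category(sim$Y1[, j], sim$Y2[, j]),
      X1 = sim$X1[, j], X2 = Xt[, j],
      phi = sim$phi, pi1 = sim$pi1[, , j], pi2 = sim$pi2[, , j],
      K = 4L, ids = sim$pedigree$id,
      family = as.character(j)
    ))
}

#' Write a simulated sample as Merlin/QTDT files
#'
#' Writes `<prefix>.ped`, `<prefix>.dat`, `<prefix>.map` (traits `endo`,
#' `disease`; markers `locus1`, `locus2`, `nullmarker`, risk/counted
#' allele coded `2`) and `<prefix>.ibd` with the realized IBD sharing of
#' every member pair, readable by [read_pedigree()] and [read_ibd()].
#'
#' @param sim a `gdt_sim`.
#' @param prefix output path prefix.
#' @return Invisibly, the four file paths.
#' @export
sim_write_files <- function(sim, prefix) {
  n <- nrow(sim$Y1)
  Fam <- sim$n_families
  al <- function(d) {  # dosage {0,.5,1} -> two allele codes ("1"/"2")
    a1 <- ifelse(d == 1, "2", ifelse(d == 0.5, "2", "1"))
    a2 <- ifelse(d == 1, "2", "1")
    cbind(a1, a2)
  }
  ped <- gdt_pedigree(
    family = rep(as.character(seq_len(Fam)), each = n),
    id = rep(sim$pedigree$id, Fam),
    father = rep(sim$pedigree$father, Fam),
    mother = rep(sim$pedigree$mother, Fam),
    sex = rep(sim$pedigree$sex, Fam)
  )
  pd <- structure(list(
    pedigree = ped,
    traits = data.frame(endo = as.integer(sim$Y1),
                        disease = as.integer(sim$Y2)),
    markers = list(locus1 = al(as.numeric(sim$X1)),
                   locus2 = al(as.numeric(sim$X2)),
                   nullmarker = al(as.numeric(sim$Xnull)))
  ), class = "gdt_ped_data")
  paths <- paste0(prefix, c(".ped", ".dat", ".map", ".ibd"))
  write_pedigree(pd, paths[1L], paths[2L], paths[3L])
  # one-hot IBD probabilities from the realized sharing (0, 1/2 or 1)
  rows <- vector("list", Fam)
  for (j in seq_len(Fam)) {
    pr <- which(upper.tri(sim$phi, diag = TRUE), arr.ind = TRUE)
    mk <- function(pim, marker) data.frame(
      family = j, id1 = sim$pedigree$id[pr[, 1L]],
      id2 = sim$pedigree$id[pr[, 2L]], marker = marker,
      p0 = as.numeric(pim[pr] == 0), p1 = as.numeric(pim[pr] == 0.5),
      p2 = as.numeric(pim[pr] == 1))
    rows[[j]] <- rbind(mk(sim$pi1[, , j], "locus1"),
                       mk(sim$pi2[, , j], "locus2"),
                       mk(sim$pi2[, , j], "nullmarker"))
  }
  tab <- do.call(rbind, rows)
  write.table(tab, paths[4L], quote = FALSE, row.names = FALSE,
              col.names = c("FAMILY", "ID1", "ID2", "MARKER",
                            "P0", "P1", "P2"))
  invisible(paths)
}
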