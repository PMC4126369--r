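# Independent reference implementations used as oracles.  These are kept
# deliberately naive (explicit loops, no shared code with the package
# internals beyond public accessors).

# Dichotomous GDT family score: S = (1/n) sum_{i affected} sum_{j not}
# (X_i - X_j), written as two explicit loops over members.
oracle_gdt_family_score <- function(x, case) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (case[i] && !case[j]) s <- s + (x[i] - x[j])
  }
  s / n
}

# Naive O(n^4) quadruple-sum variance of a weighted single-category score
# with a pairwise kernel matrix P (IBD sharing or 2*kinship, or an
# elementwise product for interaction terms) and term variance sig2.
oracle_variance_quad <- function(C, inE, P, sig2) {
  E <- which(inE); Ec <- which(!inE)
  v <- 0
  for (i in E) for (j in Ec) for (k in E) for (l in Ec) {
    v <- v + C[i, j] * C[k, l] *
      (P[i, k] + P[j, l] - P[i, l] - P[j, k])
  }
  v * sig2
}

# Pooled within-family variance of genotype columns under the kernel
# model Cov(x_i, x_k) = P_ik * sigma2: sums of squares divided by the
# kernel-corrected degrees of freedom tr(P) - 1'P1/n, pooled over
# families (reduces to n - 1 for unrelated members).
oracle_pooled_var <- function(cols, Ps) {
  num <- sum(vapply(cols, function(x) sum((x - mean(x))^2), numeric(1)))
  den <- sum(vapply(Ps, function(P)
    sum(diag(P)) - sum(P) / nrow(P), numeric(1)))
  num / den
}

# Full independent dichotomous GDT test (score, quadruple-sum variance
# with equal weights 1/n, normal p) over a list of families given as
# lists with fields x, case, P (relatedness matrix).
oracle_gdt_test <- function(fams) {
  S <- 0; V <- 0
  # variance pooled over the discordant (score-contributing) families
  disc <- Filter(function(f) any(f$case) && !all(f$case), fams)
  sig2 <- oracle_pooled_var(lapply(disc, `[[`, "x"),
                            lapply(disc, `[[`, "P"))
  for (f in fams) {
    n <- length(f$x)
    S <- S + oracle_gdt_family_score(f$x, f$case)
    C <- matrix(1 / n, n, n)
    V <- V + oracle_variance_quad(C, f$case, f$P, sig2)
  }
  z <- S / sqrt(V)
  list(S = S, V = V, Z = z, p = 2 * pnorm(-abs(z)))
}

# Random pedigree of n members: a founder couple, then each new member is
# either a child of a random existing couple or a married-in founder.
random_pedigree <- function(n, family = "1") {
  stopifnot(n >= 2)
  fa <- mo <- rep(NA_integer_, n)
  couples <- list(c(1L, 2L))
  i <- 3L
  while (i <= n) {
    if (runif(1) < 0.65 || i == n) {
      cp <- couples[[sample.int(length(couples), 1L)]]
      fa[i] <- cp[1L]; mo[i] <- cp[2L]
    } else {
      # married-in founder: forms a new couple with an existing member
      couples[[length(couples) + 1L]] <- c(sample.int(i - 1L, 1L), i)
    }
    i <- i + 1L
  }
  gdt_pedigree(family = rep(family, n), id = as.character(1:n),
               father = as.character(fa), mother = as.character(mo),
               sex = rep(0L, n))
}

# Random family_sample with gene-dropped genotypes at both loci and
# arbitrary phenotype categories; IBD matrices are the realized sharing.
random_family <- function(n, K = 2L, raf1 = 0.4, raf2 = 0.3,
                          family = "1") {
  ped <- random_pedigree(n, family)
  phi <- compute_kinship(ped)[[1L]]
  g1 <- simulate_genotypes(ped, raf1)
  g2 <- simulate_genotypes(ped, raf2)
  Y <- sample.int(K, n, replace = TRUE)
  family_sample(Y = Y, X1 = g1$dosage, X2 = g2$dosage, phi = phi,
                pi1 = g1$ibd, pi2 = g2$ibd, K = K, family = family)
}
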