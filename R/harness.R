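#' The standard test battery
#'
#' Computes p-values for the full set of evaluated tests on one sample of
#' K = 4 family samples (X1 = conditioning locus, X2 = tested marker):
#' \describe{
#'   \item{bt_1L}{joint score test of all one-locus polytomous
#'     coefficients (3 d.f., equal weights, empirical covariance
#'     kernel).}
#'   \item{b3_1L}{score test of the category-3 one-locus coefficient
#'     (model-based IBD-kernel variance).}
#'   \item{b33}{conditional test of the single interaction coefficient
#'     given locus 1 (free locus-1 coefficients, weighted pairs).}
#'   \item{be_b33}{2 d.f. conditional test under the
#'     endophenotype-to-disease model.}
#'   \item{cpoly}{6 d.f. conditional test of all locus-2 coefficients of
#'     the full two-locus model.}
#'   \item{GDT, GDTc, GDTe}{dichotomous GDT variants
#'     ([gdt_variant_test()]).}
#'   \item{cdisease, cendo}{2 d.f. conditional dichotomous two-locus
#'     tests.}
#'   \item{gee_1L, gee_b3}{GEE-based Wald tests of the one-locus model
#'     coefficients (jointly / category 3 only).}
#' }
#'
#' @param samples list of K = 4 [family_sample()] objects.
#' @param tests character vector of test names (default: all).
#' @param null `"assoc"` or `"linkage-assoc"` for the score tests.
#' @param weights weight expression for the conditional tests (`"eq6"`,
#'   the default, or `"eq7"`).
#' @return Named numeric vector of p-values.
#' @export
battery_pvalues <- function(samples,
                            tests = c("bt_1L", "b3_1L", "b33", "be_b33",
                                      "cpoly", "GDT", "GDTc", "GDTe",
                                      "cdisease", "cendo", "gee_1L",
                                      "gee_b3"),
                            null = "assoc", weights = "eq6") {
  d1L <- design_one_locus(4L)
  p <- stats::setNames(rep(NA_real_, length(tests)), tests)
  afit <- NULL
  need_afit <- any(tests %in% c("b33", "be_b33", "cpoly"))
  if (need_afit) {
    dfull <- design_full_two_locus()
    afit <- fit_polytomous(samples,
                           restrict_design(dfull, c("b11", "b21", "b31")))
  }
  for (tn in tests) {
    p[tn] <- switch(tn,
      bt_1L = gdt_test(samples, d1L, tested = c("bt1", "bt2", "bt3"),
                       weights = "equal", null = null,
                       kernel = "empirical")$p.value,
      b3_1L = gdt_test(samples, d1L, tested = "bt3", weights = "equal",
                       null = null, kernel = "model")$p.single[["bt3"]],
      b33 = {
        db33 <- design_custom(4L, data.frame(
          category = c(1L, 2L, 3L, 3L),
          term = c("X1", "X1", "X1", "X1X2"),
          label = c("b11", "b21", "b31", "b33")), name = "b33cond")
        r <- gdt_test(samples, db33, tested = "b33", weights = weights,
                      null = null, kernel = "model", alpha_fit = afit)
        r$p.single[["b33"]]
      },
      be_b33 = gdt_test(samples, design_endo_to_disease(),
                        tested = c("be", "b33"), weights = weights,
                        null = null, kernel = "empirical",
                        alpha_fit = afit)$p.value,
      cpoly = gdt_test(samples, design_full_two_locus(),
                       weights = weights, null = null,
                       kernel = "empirical", alpha_fit = afit)$p.value,
      GDT = gdt_variant_test(samples, "GDT", null = null)$p.single[[1L]],
      GDTc = gdt_variant_test(samples, "GDTc", null = null)$p.single[[1L]],
      GDTe = gdt_variant_test(samples, "GDTe", null = null)$p.single[[1L]],
      cdisease = gdt_variant_test(samples, "cdisease", null = null,
                                  weights = weights)$p.value,
      cendo = gdt_variant_test(samples, "cendo", null = null,
                               weights = weights)$p.value,
      gee_1L = gee_wald_test(samples, d1L,
                             c("bt1", "bt2", "bt3"))$p.value,
      gee_b3 = gee_wald_test(samples, d1L, "bt3")$p.value,
      stop("unknown test: ", tn)
    )
  }
  p
}

# counter-based per-replicate seed derived from one master seed
.replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + r * 97003) %% 2147483629)
}

#' Run a Type-I-error / power experiment
#'
#' Simulates `replicates` samples of ascertained families under a
#' scenario, applies the test battery to the requested target marker(s)
#' of each replicate, and tallies rejection proportions at nominal levels
#' 0.01 and 0.05.  Testing the null (linkage-equilibrium) marker at locus
#' 2 measures Type I error in presence of linkage; testing the causal
#' locus-2 variant measures power.  Replicates that fail (e.g., a
#' singular fit) are logged and skipped.
#'
#' @param scenario a [simulation_scenario()].
#' @param replicates number of replicate samples.
#' @param seed master seed; per-replicate seeds are derived by a
#'   counter-based splitter and recorded in the report.
#' @param tests test names as in [battery_pvalues()].
#' @param targets `"null"`, `"causal"`, or both (sharing the simulated
#'   replicates).
#' @param n_families families per replicate.
#' @param null,weights passed to [battery_pvalues()].
#' @return Object of class `gdt_experiment` (or a named list of them when
#'   several targets are requested): p-value matrix, rejection table with
#'   binomial standard errors, seeds and runtime.
#' @export
run_experiment <- function(scenario, replicates = 250L, seed = 1L,
                           tests = c("bt_1L", "b3_1L", "b33", "be_b33",
                                     "cpoly", "GDT", "GDTc", "GDTe",
                                     "cdisease", "cendo", "gee_1L",
                                     "gee_b3"),
                           targets = "null",
                           n_families = scenario$n_families,
                           null = "assoc", weights = "eq6") {
  stopifnot(all(targets %in% c("null", "causal")))
  t0 <- proc.time()[["elapsed"]]
  seeds <- vapply(seq_len(replicates), function(r)
    .replicate_seed(seed, r), integer(1L))
  P <- lapply(targets, function(tg)
    matrix(NA_real_, replicates, length(tests),
           dimnames = list(NULL, tests)))
  names(P) <- targets
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    set.seed(seeds[r])
    ok <- tryCatch({
      sim <- simulate_sample(scenario, n_families)
      for (tg in targets) {
        smp <- sim_to_samples(sim, tested = tg)
        P[[tg]][r, ] <- suppressWarnings(
          battery_pvalues(smp, tests, null = null, weights = weights))
      }
      TRUE
    }, error = function(e) {
      message("replicate ", r, " failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) n_failed <- n_failed + 1L
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  out <- lapply(targets, function(tg) {
    pm <- P[[tg]]
    rej <- function(alpha) {
      used <- colSums(!is.na(pm))
      prop <- colSums(pm < alpha, na.rm = TRUE) / pmax(used, 1L)
      data.frame(test = tests, level = alpha, rejection = prop,
                 se = sqrt(prop * (1 - prop) / pmax(used, 1L)),
                 replicates = used, row.names = NULL)
    }
    structure(list(
      pvalues = pm,
      rejections = rbind(rej(0.01), rej(0.05)),
      target = tg, replicates = replicates, n_failed = n_failed,
      seed = seed, seeds = seeds,
      scenario_mixture = scenario$mixture,
      elapsed = elapsed
    ), class = "gdt_experiment")
  })
  names(out) <- targets
  if (length(out) == 1L) out[[1L]] else out
}

#' @rdname run_experiment
#' @param ... passed to [run_experiment()].
#' @export
run_type1 <- function(scenario, replicates = 250L, seed = 1L, ...) {
  run_experiment(scenario, replicates, seed, targets = "null", ...)
}

#' @rdname run_experiment
#' @export
run_power <- function(scenario, replicates = 250L, seed = 1L, ...) {
  run_experiment(scenario, replicates, seed, targets = "causal", ...)
}

#' @export
print.gdt_experiment <- function(x, ...) {
  cat("<gdt_experiment> target: ", x$target, " marker, ",
      x$replicates, " replicates (", x$n_failed, " failed), ",
      if (x$scenario_mixture) "two-population mixture"
      else "homogeneous population",
      ", seed ", x$seed, ", ", sprintf("%.1f", x$elapsed), " s\n",
      sep = "")
  tab <- x$rejections
  tab$rejection <- sprintf("%.3f", tab$rejection)
  tab$se <- sprintf("%.4f", tab$se)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Marker scan from Merlin/QTDT files
#'
#' Runs the requested model's score test(s) for each tested marker,
#' optionally conditioning on an established risk marker, and returns (and
#' optionally writes) a TSV-ready result table with one row per marker per
#' test.  No multiple-testing adjustment is applied; raw p-values are
#' reported.
#'
#' @param ped_data a `gdt_ped_data` from [read_pedigree()] (or a path to
#'   a `.ped` file, with `dat_path` supplied).
#' @param trait_spec as in [build_family_samples()].
#' @param model `"onelocus"`, `"full2locus"`, `"endo2disease"` or
#'   `"dichot2locus"`.
#' @param markers tested marker names (default: all markers except the
#'   conditioning marker).
#' @param conditioning conditioning (locus 1) marker name; required by
#'   the two-locus models.
#' @param dat_path `.dat` path when `ped_data` is a file path.
#' @param ibd_path optional IBD file path ([read_ibd()] layout) used for
#'   the association-only null.
#' @param null,weights passed to [gdt_test()].
#' @param counted named vector of counted alleles per marker.
#' @param out optional output TSV path.
#' @return A data frame with columns marker, model, test, S, stat, df, p,
#'   null, weights, n_informative.
#' @export
gdt_scan <- function(ped_data, trait_spec,
                     model = c("onelocus", "full2locus", "endo2disease",
                               "dichot2locus"),
                     markers = NULL, conditioning = NULL,
                     dat_path = NULL, ibd_path = NULL,
                     null = c("assoc", "linkage-assoc"), weights = "eq6",
                     counted = NULL, out = NULL) {
  model <- match.arg(model)
  null <- match.arg(null)
  if (is.character(ped_data))
    ped_data <- read_pedigree(ped_data, dat_path)
  if (is.null(markers))
    markers <- setdiff(names(ped_data$markers), conditioning)
  two_locus <- model != "onelocus"
  if (two_locus && is.null(conditioning))
    stop("model ", model, " requires a conditioning marker")
  design <- switch(model,
    onelocus = design_one_locus(if (!is.null(trait_spec$Y)) 2L else 4L),
    full2locus = design_full_two_locus(),
    endo2disease = design_endo_to_disease(),
    dichot2locus = design_dichotomous_two_locus())
  kinship <- compute_kinship(ped_data$pedigree)
  rows <- list()
  for (m in markers) {
    if (!is.null(conditioning) && m == conditioning) {
      warning("tested marker equals conditioning marker (", m,
              "); degenerate design skipped")
      rows[[m]] <- data.frame(
        marker = m, model = model, test = "degenerate", S = NA_real_,
        stat = NA_real_, df = NA_integer_, p = NA_real_, null = null,
        weights = weights, n_informative = NA_integer_,
        stringsAsFactors = FALSE)
      next
    }
    loci <- c(X1 = if (two_locus) conditioning, X2 = m)
    ibd <- NULL
    if (!is.null(ibd_path)) {
      ibd <- list(X2 = read_ibd(ibd_path, m, kinship))
      if (two_locus)
        ibd$X1 <- read_ibd(ibd_path, conditioning, kinship)
    }
    samples <- build_family_samples(ped_data, trait_spec, loci,
                                    counted = counted, kinship = kinship,
                                    ibd = ibd)
    tested <- design$conditional_null
    res <- gdt_test(samples, design, tested = tested, weights =
                      if (is.null(tested)) "equal" else weights,
                    null = null)
    test_name <- if (is.null(tested)) paste0(model, ":all")
                 else paste0(model, ":conditional")
    rows[[m]] <- result_row(res, marker = m, test = test_name)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out))
    write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
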