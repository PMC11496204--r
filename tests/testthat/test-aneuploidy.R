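# build a log-CPM-like matrix directly for regression unit tests
lc_matrix <- function(x, y, ids = c("d", "t")) {
  m <- cbind(x, y)
  dimnames(m) <- list(sprintf("g%03d", seq_along(x)), ids)
  m
}

test_that("the identity pair gives slope 1, intercept 0, zero se", {
  x <- withr::with_seed(1, rnorm(40, 8, 2))
  lc <- lc_matrix(x, x)
  gm <- data.frame(gene_id = rownames(lc), chromosome_id = "chr1")
  fit <- chromosome_regression(lc, gm, c("d", "t"), "chr1")
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$slope_se, 0)
  expect_equal(fit$n_genes, 40)
})

test_that("a constant log-ratio moves the intercept, not the slope", {
  # the pure-dosage case: OLS slope is blind to it, which is why calls are
  # based on the median log-ratio statistic instead
  delta <- log2(2 / 3)
  x <- withr::with_seed(2, rnorm(60, 8, 2))
  lc <- lc_matrix(x, x + delta)
  gm <- data.frame(gene_id = rownames(lc), chromosome_id = "chr1")
  fit <- chromosome_regression(lc, gm, c("d", "t"), "chr1")
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, delta)
})

test_that("closed-form OLS agrees with grid-search and lm oracles", {
  for (s in 1:20) {
    dat <- withr::with_seed(s, {
      x <- rnorm(50, 6, 3)
      a <- runif(1, -3, 3); b <- runif(1, -2, 2)
      list(x = x, y = a + b * x + rnorm(50, 0, 0.5))
    })
    lc <- lc_matrix(dat$x, dat$y)
    gm <- data.frame(gene_id = rownames(lc), chromosome_id = "chr1")
    fit <- chromosome_regression(lc, gm, c("d", "t"), "chr1")
    oracle <- brute_force_ols(dat$x, dat$y)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-5)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-5)
    ref <- summary(lm(y ~ x, data.frame(x = dat$x, y = dat$y)))
    expect_equal(fit$slope, unname(ref$coefficients["x", "Estimate"]))
    expect_equal(fit$slope_se, unname(ref$coefficients["x", "Std. Error"]))
  }
})

test_that("degenerate chromosomes yield explicit undefined records", {
  x <- withr::with_seed(3, rnorm(30, 8, 2))
  lc <- lc_matrix(x, x)
  gm <- data.frame(gene_id = rownames(lc),
                   chromosome_id = rep(c("big", "small"), c(25, 5)))
  fit <- chromosome_regression(lc, gm, c("d", "t"), "small")
  expect_true(is.na(fit$slope))
  expect_equal(fit$reason, "too_few_genes")
  lc2 <- lc_matrix(rep(5, 30), x)
  fit2 <- chromosome_regression(lc2, gm, c("d", "t"), "big")
  expect_equal(fit2$reason, "zero_variance")
  expect_error(chromosome_regression(lc, gm, c("d", "zzz"), "big"), "zzz")
})

test_that("dosage statistics are zero for a self-pair and depth-invariant", {
  sim <- simulate_dataset(pair_config(n_genes = 2000, seed = 4))
  lc <- log_cpm(sim$counts)
  self <- dosage_statistics(lc, sim$genemap,
                            rep(sim$samples$sample_id[1], 2))
  expect_true(all(self == 0))

  # multiplying one library by an integer leaves CPM, hence the statistic,
  # exactly unchanged
  scaled <- sim$counts
  scaled[, 1] <- scaled[, 1] * 7L
  expect_identical(
    dosage_statistics(log_cpm(sim$counts), sim$genemap,
                      sim$samples$sample_id),
    dosage_statistics(log_cpm(scaled), sim$genemap,
                      sim$samples$sample_id))
})

test_that("robust z is invariant to a global shift of the triploid sample", {
  sim <- simulate_dataset(pair_config(n_genes = 3000, seed = 6))
  lc <- log_cpm(filter_low_expression(sim$counts))
  med <- dosage_statistics(lc, sim$genemap, sim$samples$sample_id)
  lc2 <- lc
  lc2[, 2] <- lc2[, 2] + 1.7
  med2 <- dosage_statistics(lc2, sim$genemap, sim$samples$sample_id)
  expect_equal(call_aneuploidy(med2)$robust_z, call_aneuploidy(med)$robust_z)
})

test_that("aneuploidy calls handle degenerate and insufficient baselines", {
  v <- setNames(rep(0.2, 10), paste0("chr", 1:10))
  calls <- call_aneuploidy(v)
  expect_true(all(calls$robust_z == 0))
  expect_false(any(calls$flagged))

  expect_error(call_aneuploidy(v[1:4]), "5 chromosomes")

  # zero MAD with one real deviation: fall back to the effect floor
  v2 <- v
  v2["chr3"] <- 0.2 + log2(2 / 3)
  v2[setdiff(names(v2), "chr3")] <- 0.2  # nine identical values -> MAD 0
  expect_warning(calls2 <- call_aneuploidy(v2), "effect floor")
  expect_true(calls2$flagged[calls2$chromosome_id == "chr3"])
  expect_equal(sum(calls2$flagged), 1)
})

test_that("a planted monosomy deviates by log2(2/3) regardless of the
           chromosome's expression share", {
  for (f in c(0.1, 0.25)) {
    cfg <- pair_config(n_genes = 5000, seed = round(1000 * f),
                       copy_number = 2,
                       chromosome_weights = c(f, rep((1 - f) / 9, 9)))
    sim <- simulate_dataset(cfg)
    lc <- log_cpm(filter_low_expression(sim$counts))
    med <- dosage_statistics(lc, sim$genemap, sim$samples$sample_id)
    calls <- call_aneuploidy(med)
    dev <- med["chr1"] - attr(calls, "baseline")
    expect_equal(unname(dev), log2(2 / 3), tolerance = 0.05)
    expect_true(calls$flagged[calls$chromosome_id == "chr1"])
    expect_equal(sum(calls$flagged), 1)
  }
})

test_that("flags follow the chromosome carrying the event and track sign", {
  for (chr in c("chr2", "chr7")) {
    sim <- simulate_dataset(pair_config(n_genes = 5000, seed = 31,
                                        copy_number = 4,
                                        event_chromosome = chr))
    lc <- log_cpm(filter_low_expression(sim$counts))
    med <- dosage_statistics(lc, sim$genemap, sim$samples$sample_id)
    calls <- call_aneuploidy(med)
    hit <- calls$chromosome_id == chr
    expect_true(calls$flagged[hit])
    expect_gt(calls$robust_z[hit], 0)  # gain -> positive z
    expect_equal(sum(calls$flagged), 1)
  }
})

test_that("screen output has one row per pair and chromosome", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 1000, design = default_design(n_per_ploidy = 2), seed = 8,
    dispersion = Inf, lib_size_cv = 0))
  lc <- log_cpm(filter_low_expression(sim$counts))
  pr <- match_pairs(sim$samples)
  scr <- screen_all_pairs(lc, sim$genemap, pr)
  expect_equal(nrow(scr), nrow(pr) * 10)
  expect_identical(names(scr),
                   c("pair_id", "chromosome_id", "n_genes", "slope",
                     "intercept", "slope_se", "median_log_ratio",
                     "robust_z", "flagged"))
  summary <- attr(scr, "pair_summary")
  expect_equal(nrow(summary), nrow(pr))

  # self-pairs: exact identity lines and no flags
  self <- data.frame(pair_id = "self1",
                     diploid_id = pr$diploid_id[1],
                     triploid_id = pr$diploid_id[1],
                     site = "S", cohort = "C", dam = "D")
  scr_self <- screen_all_pairs(lc, sim$genemap, self)
  expect_true(all(scr_self$slope == 1))
  expect_false(any(scr_self$flagged))
})

test_that("detection sensitivity increases with dosage effect size", {
  # dosage compensation shrinks the planted effect below the call floor:
  # a fully proportional monosomy must be detected at least as often
  sens <- vapply(c(0.3, 1), function(comp) {
    hits <- 0
    for (r in 1:10) {
      cfg <- pair_config(n_genes = 3000, seed = 5000 + r, copy_number = 2,
                         dosage_compensation = comp)
      sim <- simulate_dataset(cfg)
      lc <- log_cpm(filter_low_expression(sim$counts))
      med <- dosage_statistics(lc, sim$genemap, sim$samples$sample_id)
      hits <- hits + call_aneuploidy(med)$flagged[1]
    }
    hits / 10
  }, numeric(1))
  expect_lte(sens[1], sens[2])
  expect_equal(sens[2], 1)        # |log2(2/3)| is far above the floor
  expect_lt(sens[1], 0.5)         # (2/3)^0.3 is below the 15% floor
})

test_that("power analysis reports null FPR and planted-event sensitivity", {
  scen <- data.frame(scenario = c("null", "monosomy"), copy_number = c(3, 2))
  pw <- power_analysis(scen, n_reps = 5, seed = 77,
                       template = pair_config(n_genes = 2000))
  expect_equal(nrow(pw), 2)
  expect_true(is.na(pw$sensitivity[1]))
  expect_equal(pw$sensitivity[2], 1)
  expect_true(all(pw$fpr <= 0.05))
  expect_error(power_analysis(scen, n_reps = 0), "n_reps")
})
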