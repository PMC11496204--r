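test_that("configuration rejects invalid fields with messages naming them", {
  expect_error(simulation_config(chromosome_weights = c(0.5, 0.6),
                                 n_chromosomes = 2),
               "chromosome_weights")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(design = data.frame()), "design")
  expect_error(simulation_config(frac_affected_genes = 2),
               "frac_affected_genes")
  expect_error(
    simulation_config(aneuploidy_events = data.frame(
      sample_id = "a", chromosome_id = "chr1", copy_number = 7)),
    "copy_number")
})

test_that("the same seed reproduces the dataset exactly", {
  cfg <- simulation_config(n_genes = 300,
                           design = default_design(n_per_ploidy = 2),
                           seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$karyotype, s2$karyotype)
  expect_identical(s1$genemap, s2$genemap)
  s3 <- simulate_dataset(simulation_config(n_genes = 300,
                                           design = default_design(2),
                                           seed = 100))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("simulated shapes, ids, and gene apportionment follow the config", {
  cfg <- simulation_config(n_genes = 101, n_chromosomes = 3,
                           chromosome_weights = c(0.5, 0.3, 0.2),
                           design = default_design(n_per_ploidy = 2))
  sim <- simulate_dataset(cfg)
  expect_equal(dim(sim$counts), c(101, 48))  # 12 cells x 2 ploidies x 2
  expect_equal(as.vector(table(sim$genemap$chromosome_id)[c("chr1", "chr2", "chr3")]),
               c(51, 30, 20))
  expect_identical(rownames(sim$counts), sim$genemap$gene_id)
  expect_identical(colnames(sim$counts), sim$samples$sample_id)
})

test_that("library sizes are matched in expectation", {
  lib <- 1e5
  des <- default_design(n_per_ploidy = 1)[1, ]
  tot <- 0
  for (s in 1:100) {
    sim <- simulate_dataset(simulation_config(
      n_genes = 300, design = des, lib_size_mean = lib, lib_size_cv = 0,
      dispersion = 20, seed = s))
    tot <- tot + colSums(sim$counts)
  }
  expect_lt(max(abs(tot / 100 - lib)) / lib, 0.01)
})

test_that("whole-genome triploidy cancels under CPM normalization", {
  # no aneuploidy, no covariate effects: per-chromosome mean CPM of the
  # triploid matches the diploid even though every transcript is at 3 copies
  sim <- simulate_dataset(pair_config(n_genes = 5000, seed = 5))
  cm <- cpm(sim$counts)
  by_chr <- split(seq_len(nrow(cm)), sim$genemap$chromosome_id)
  ratios <- vapply(by_chr, function(i) mean(cm[i, 2]) / mean(cm[i, 1]),
                   numeric(1))
  expect_true(all(abs(ratios - 1) < 0.02))
})

test_that("a planted monosomy produces the closed-form CPM dosage ratios", {
  # chr1 carries f = 0.1 of per-copy expression; triploid carries chr1 at
  # copy 2. Expected CPM ratios: on-chromosome 2/(3-f), elsewhere 3/(3-f).
  f <- 0.1
  rat_on <- rat_off <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    cfg <- pair_config(n_genes = 5000, seed = 200 + r, copy_number = 2,
                       chromosome_weights = c(f, rep((1 - f) / 9, 9)),
                       baseline_log_sd = 0)
    sim <- simulate_dataset(cfg)
    cm <- cpm(sim$counts)
    on <- sim$genemap$chromosome_id == "chr1"
    rat_on <- rat_on + mean(cm[on, 2]) / mean(cm[on, 1])
    rat_off <- rat_off + mean(cm[!on, 2]) / mean(cm[!on, 1])
  }
  expect_equal(rat_on / reps, 2 / (3 - f), tolerance = 0.01)
  expect_equal(rat_off / reps, 3 / (3 - f), tolerance = 0.01)
})

test_that("karyotype truth defaults to ploidy and round-trips events", {
  ev <- data.frame(sample_id = c("GrandIsle_AU_CL_3n_01",
                                 "GrandIsle_AU_CL_2n_02"),
                   chromosome_id = c("chr4", "chr9"),
                   copy_number = c(2L, 3L), stringsAsFactors = FALSE)
  cfg <- simulation_config(n_genes = 100,
                           design = default_design(n_per_ploidy = 2)[1, ],
                           aneuploidy_events = ev, seed = 3)
  sim <- simulate_dataset(cfg)
  base2 <- sim$karyotype[sim$samples$ploidy == "2n", ]
  base3 <- sim$karyotype[sim$samples$ploidy == "3n", ]
  expect_true(all(base2[!(rownames(base2) %in% ev$sample_id), ] == 2L))
  expect_true(all(base3[!(rownames(base3) %in% ev$sample_id), ] == 3L))
  rec <- karyotype_events(sim$karyotype, sim$samples)
  expect_equal(rec[order(rec$sample_id), ],
               ev[order(ev$sample_id), ], ignore_attr = TRUE)
})

test_that("full dosage compensation erases the copy-number signal", {
  cfg1 <- pair_config(n_genes = 3000, seed = 17, copy_number = 2,
                      baseline_log_sd = 0.5)
  cfg0 <- cfg1; cfg0$dosage_compensation <- 0
  on <- function(sim) sim$genemap$chromosome_id == "chr1"
  ratio_on <- function(cfg) {
    sim <- simulate_dataset(cfg)
    cm <- cpm(sim$counts)
    mean(cm[on(sim), 2]) / mean(cm[on(sim), 1])
  }
  expect_lt(ratio_on(cfg1), 0.75)          # proportional dosage: ~2/(3-f)
  expect_equal(ratio_on(cfg0), 1, tolerance = 0.05)  # compensated: no signal
})

test_that("events referencing unknown samples or chromosomes are rejected", {
  cfg <- simulation_config(n_genes = 50,
                           design = default_design(n_per_ploidy = 1)[1, ],
                           aneuploidy_events = data.frame(
                             sample_id = "nope", chromosome_id = "chr1",
                             copy_number = 2))
  expect_error(simulate_dataset(cfg), "unknown sample_id")
})
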