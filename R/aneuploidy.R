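# closed-form bivariate OLS with intercept; se undefined for n <= 2 -> 0
.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  sxx <- sum(dx^2)
  slope <- sum(dx * (y - my)) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  se <- if (n > 2) sqrt(sum(resid^2) / (n - 2) / sxx) else 0
  list(slope = slope, intercept = intercept, slope_se = se)
}

.pair_ids <- function(pair) {
  if (is.list(pair)) pair <- unlist(pair)
  if (length(pair) != 2)
    stop("pair must give exactly (diploid_id, triploid_id)")
  as.character(pair)
}

.pair_columns <- function(logcpm, pair) {
  ids <- .pair_ids(pair)
  missing_ids <- setdiff(ids, colnames(logcpm))
  if (length(missing_ids))
    stop("sample(s) not in the expression matrix: ",
         paste(missing_ids, collapse = ", "))
  list(x = logcpm[, ids[1]], y = logcpm[, ids[2]])
}

# gene row indices per chromosome, restricted to genes present in the matrix
.chr_index <- function(logcpm, genemap) {
  hit <- genemap$gene_id %in% rownames(logcpm)
  gm <- genemap[hit, , drop = FALSE]
  idx <- match(gm$gene_id, rownames(logcpm))
  split(idx, gm$chromosome_id)[sort(unique(gm$chromosome_id))]
}

#' Per-chromosome regression of triploid on diploid log-CPM
#'
#' For the genes on one chromosome, fits an ordinary least-squares line of
#' the triploid sample's log-CPM (y) on the diploid sample's log-CPM (x),
#' with intercept. This is the slope tabulated per chromosome per pair in a
#' dosage screen. Note that a uniform chromosome-wide dosage change adds a
#' constant to y and therefore moves the intercept, not the slope, of this
#' fit; see [call_aneuploidy()] for the statistic the flags are based on.
#'
#' @param logcpm log-CPM matrix from [log_cpm()].
#' @param genemap data.frame `gene_id`, `chromosome_id`.
#' @param pair character vector `(diploid_id, triploid_id)`.
#' @param chromosome_id chromosome to regress.
#' @param min_genes minimum genes for a defined fit (default 20).
#' @return list with `slope`, `intercept`, `slope_se`, `n_genes`, and
#'   `reason` (`NA` when defined, otherwise why the fit is undefined:
#'   `"too_few_genes"` or `"zero_variance"`).
#' @export
chromosome_regression <- function(logcpm, genemap, pair, chromosome_id,
                                  min_genes = 20) {
  cols <- .pair_columns(logcpm, pair)
  idx <- .chr_index(logcpm, genemap)[[as.character(chromosome_id)]]
  n <- length(idx)
  undefined <- function(reason)
    list(slope = NA_real_, intercept = NA_real_, slope_se = NA_real_,
         n_genes = n, reason = reason)
  if (is.null(idx) || n < min_genes) return(undefined("too_few_genes"))
  x <- cols$x[idx]; y <- cols$y[idx]
  if (stats::var(x) == 0) return(undefined("zero_variance"))
  c(.ols(x, y), list(n_genes = n, reason = NA_character_))
}

#' Per-chromosome median log-expression ratio for one pair
#'
#' For each chromosome, the median over its genes of
#' `logCPM(triploid) - logCPM(diploid)`. Library-size normalization makes
#' this statistic exactly invariant to rescaling either sample's library,
#' so a chromosome-wide shift reflects a copy-number (dosage) difference,
#' not sequencing depth.
#'
#' @inheritParams chromosome_regression
#' @return named numeric vector over chromosomes; `NA` where a chromosome
#'   has fewer than `min_genes` genes.
#' @export
dosage_statistics <- function(logcpm, genemap, pair, min_genes = 20) {
  cols <- .pair_columns(logcpm, pair)
  ratio <- cols$y - cols$x
  idx <- .chr_index(logcpm, genemap)
  vapply(idx, function(i) {
    if (length(i) < min_genes) NA_real_ else stats::median(ratio[i])
  }, numeric(1))
}

#' Flag chromosomes with outlying dosage ratios
#'
#' Centers the per-chromosome median log-ratios at their cross-chromosome
#' median (the within-pair baseline, which absorbs any global expression or
#' depth difference including whole-genome triploidy) and scales by
#' 1.4826 x MAD. A chromosome is flagged when both `|robust_z| >=
#' z_threshold` and the absolute deviation from baseline reaches
#' `effect_floor_log2`; the floor guards against flagging minute deviations
#' when the MAD is very small. A copy-number gain gives a positive
#' `robust_z`, a loss a negative one (a 2-of-3 monosomy in a triploid sits
#' at `log2(2/3) ~ -0.585` below baseline).
#'
#' @param median_log_ratios named vector from [dosage_statistics()].
#' @param z_threshold robust z cutoff (default 3).
#' @param effect_floor_log2 minimum absolute log2 deviation (default
#'   `log2(1.15)`, a 15% dosage change).
#' @return data.frame with one row per chromosome: `chromosome_id`,
#'   `median_log_ratio`, `robust_z`, `flagged`; attribute `baseline` holds
#'   the cross-chromosome median.
#' @export
call_aneuploidy <- function(median_log_ratios, z_threshold = 3,
                            effect_floor_log2 = log2(1.15)) {
  v <- median_log_ratios
  def <- !is.na(v)
  if (sum(def) < 5)
    stop("need at least 5 chromosomes with defined statistics to set a baseline (got ",
         sum(def), ")")
  baseline <- stats::median(v[def])
  dev <- v - baseline
  scale <- stats::mad(v[def])  # 1.4826 * median absolute deviation
  if (scale == 0) {
    z <- ifelse(dev == 0, 0, sign(dev) * Inf)
    if (any(dev[def] != 0))
      warning("MAD of chromosome dosage ratios is zero; flagging on the effect floor only",
              call. = FALSE)
    flagged <- abs(dev) >= effect_floor_log2
  } else {
    z <- dev / scale
    flagged <- abs(z) >= z_threshold & abs(dev) >= effect_floor_log2
  }
  out <- data.frame(chromosome_id = names(v),
                    median_log_ratio = unname(v),
                    robust_z = unname(z),
                    flagged = unname(flagged),
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- baseline
  out
}

#' Screen all matched pairs for chromosome-level dosage deviations
#'
#' Applies [chromosome_regression()], [dosage_statistics()] and
#' [call_aneuploidy()] to every pair, returning one row per pair x
#' chromosome. Chromosomes with undefined statistics (too few genes or
#' degenerate x) appear as explicit rows with `NA` values, never dropped.
#'
#' @param logcpm log-CPM matrix.
#' @param genemap data.frame `gene_id`, `chromosome_id`.
#' @param pairs data.frame from [match_pairs()].
#' @param z_threshold,effect_floor_log2 see [call_aneuploidy()].
#' @param min_genes see [chromosome_regression()].
#' @return data.frame with columns `pair_id`, `chromosome_id`, `n_genes`,
#'   `slope`, `intercept`, `slope_se`, `median_log_ratio`, `robust_z`,
#'   `flagged`; attribute `pair_summary` gives per-pair flag counts and an
#'   `euploid` verdict (TRUE iff zero flags).
#' @export
screen_all_pairs <- function(logcpm, genemap, pairs, z_threshold = 3,
                             effect_floor_log2 = log2(1.15), min_genes = 20) {
  if (nrow(pairs) == 0) stop("pairs table is empty")
  idx <- .chr_index(logcpm, genemap)
  chroms <- names(idx)
  res <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    x <- logcpm[, pairs$diploid_id[p]]
    y <- logcpm[, pairs$triploid_id[p]]
    ratio <- y - x
    fits <- lapply(idx, function(i) {
      n <- length(i)
      if (n < min_genes)
        return(list(slope = NA_real_, intercept = NA_real_,
                    slope_se = NA_real_, n_genes = n,
                    median_log_ratio = NA_real_))
      xi <- x[i]
      med <- stats::median(ratio[i])
      if (stats::var(xi) == 0)
        return(list(slope = NA_real_, intercept = NA_real_,
                    slope_se = NA_real_, n_genes = n,
                    median_log_ratio = med))
      c(.ols(xi, y[i]), list(n_genes = n, median_log_ratio = med))
    })
    med <- vapply(fits, `[[`, numeric(1), "median_log_ratio")
    calls <- call_aneuploidy(med, z_threshold = z_threshold,
                             effect_floor_log2 = effect_floor_log2)
    res[[p]] <- data.frame(
      pair_id = pairs$pair_id[p],
      chromosome_id = chroms,
      n_genes = vapply(fits, `[[`, numeric(1), "n_genes"),
      slope = vapply(fits, `[[`, numeric(1), "slope"),
      intercept = vapply(fits, `[[`, numeric(1), "intercept"),
      slope_se = vapply(fits, `[[`, numeric(1), "slope_se"),
      median_log_ratio = calls$median_log_ratio,
      robust_z = calls$robust_z,
      flagged = calls$flagged,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  n_flagged <- vapply(split(out$flagged, out$pair_id)[pairs$pair_id],
                      function(f) sum(f, na.rm = TRUE), numeric(1))
  attr(out, "pair_summary") <- data.frame(
    pair_id = pairs$pair_id, n_flagged = unname(n_flagged),
    euploid = unname(n_flagged) == 0, stringsAsFactors = FALSE)
  out
}

#' Sensitivity and false-positive rate of the screen by simulation
#'
#' For each scenario (a chromosome-1 copy number planted in the triploid of
#' a simulated diploid/triploid pair), simulates `n_reps` independent
#' pairs, runs the full filter -> log-CPM -> screen pipeline, and reports
#' the fraction of planted events flagged (sensitivity) and the fraction of
#' euploid chromosomes flagged (false-positive rate), with binomial
#' standard errors. Copy number 3 is the euploid null: sensitivity is `NA`
#' and every chromosome counts toward the FPR.
#'
#' @param scenarios data.frame with columns `scenario` (label) and
#'   `copy_number` (integer in 1..4; 3 = null).
#' @param n_reps replicates per scenario.
#' @param seed integer; replicate r of scenario s uses seed
#'   `seed + 10000 * s + r`.
#' @param template a [simulation_config()] whose gene/noise parameters are
#'   reused; its design is replaced by a single one-diploid/one-triploid
#'   cell.
#' @param event_chromosome chromosome carrying the planted event.
#' @param z_threshold,effect_floor_log2,min_genes screen parameters.
#' @param min_cpm,min_fraction low-expression filter parameters.
#' @return data.frame: `scenario`, `copy_number`, `n_reps`, `sensitivity`,
#'   `sensitivity_se`, `fpr`, `fpr_se`.
#' @export
power_analysis <- function(scenarios, n_reps = 50, seed = 1,
                           template = simulation_config(),
                           event_chromosome = "chr1",
                           z_threshold = 3,
                           effect_floor_log2 = log2(1.15),
                           min_genes = 20, min_cpm = 5, min_fraction = 0.8) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  design1 <- template$design[1, , drop = FALSE]
  design1$n_diploid <- 1L
  design1$n_triploid <- 1L
  rows <- lapply(seq_len(nrow(scenarios)), function(s) {
    cn <- as.integer(scenarios$copy_number[s])
    hits <- logical(n_reps)
    fp <- 0L; fp_n <- 0L
    for (r in seq_len(n_reps)) {
      cfg <- template
      cfg$design <- design1
      cfg$seed <- as.integer(seed + 10000 * s + r)
      trip_id <- .build_sample_table(design1)
      trip_id <- trip_id$sample_id[trip_id$ploidy == "3n"]
      cfg$aneuploidy_events <- if (cn != 3L)
        data.frame(sample_id = trip_id, chromosome_id = event_chromosome,
                   copy_number = cn, stringsAsFactors = FALSE) else NULL
      sim <- simulate_dataset(cfg)
      lc <- log_cpm(filter_low_expression(sim$counts, min_cpm, min_fraction))
      pr <- match_pairs(sim$samples)
      scr <- screen_all_pairs(lc, sim$genemap, pr, z_threshold,
                              effect_floor_log2, min_genes)
      ev <- scr$chromosome_id == event_chromosome
      if (cn != 3L) {
        hits[r] <- isTRUE(scr$flagged[ev])
        fp <- fp + sum(scr$flagged[!ev], na.rm = TRUE)
        fp_n <- fp_n + sum(!is.na(scr$flagged[!ev]))
      } else {
        fp <- fp + sum(scr$flagged, na.rm = TRUE)
        fp_n <- fp_n + sum(!is.na(scr$flagged))
      }
    }
    sens <- if (cn != 3L) mean(hits) else NA_real_
    fpr <- fp / fp_n
    data.frame(
      scenario = scenarios$scenario[s], copy_number = cn, n_reps = n_reps,
      sensitivity = sens,
      sensitivity_se = if (cn != 3L) sqrt(sens * (1 - sens) / n_reps)
                       else NA_real_,
      fpr = fpr, fpr_se = sqrt(fpr * (1 - fpr) / fp_n),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
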