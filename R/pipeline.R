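#' Assemble a pipeline run configuration
#'
#' A run either simulates its inputs (give `simulate` a
#' [simulation_config()]) or reads them from files (`counts_file`,
#' `genemap_file`, `samples_file`). All analysis parameters default to the
#' package-wide defaults.
#'
#' @param seed global integer seed; the only entropy source of a run.
#' @param simulate `NULL` or a [simulation_config()].
#' @param counts_file,genemap_file,samples_file input paths when not
#'   simulating; `counts_format` is `"auto"`, `"tsv"` or `"mtx"`.
#' @param min_cpm,min_fraction low-expression filter (see
#'   [filter_low_expression()]).
#' @param pseudocount pseudocount for [log_cpm()].
#' @param pair_strategy `"ordered"` or `"random"` (see [match_pairs()]).
#' @param z_threshold,effect_floor_log2,min_genes aneuploidy screen
#'   parameters (see [call_aneuploidy()], [chromosome_regression()]).
#' @param n_components,weighting shift metric parameters (see
#'   [transcriptomic_shift()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       simulate = NULL,
                       counts_file = NULL, genemap_file = NULL,
                       samples_file = NULL, counts_format = "auto",
                       min_cpm = 5, min_fraction = 0.8,
                       pseudocount = 1,
                       pair_strategy = "ordered",
                       z_threshold = 3,
                       effect_floor_log2 = log2(1.15),
                       min_genes = 20,
                       n_components = 2,
                       weighting = "fraction") {
  if (is.null(simulate) &&
      (is.null(counts_file) || is.null(genemap_file) || is.null(samples_file)))
    stop("either provide a simulation config or all three input files ",
         "(counts_file, genemap_file, samples_file)")
  if (!is.null(simulate) && !inherits(simulate, "simulation_config"))
    stop("simulate must be NULL or a simulation_config object")
  # validate numeric parameters against their operations' preconditions now
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (z_threshold <= 0) stop("z_threshold must be positive")
  if (effect_floor_log2 < 0) stop("effect_floor_log2 must be nonnegative")
  if (min_genes < 2) stop("min_genes must be at least 2")
  if (n_components < 1) stop("n_components must be at least 1")
  weighting <- match.arg(weighting, c("fraction", "sqrt", "none"))
  pair_strategy <- match.arg(pair_strategy, c("ordered", "random"))
  structure(list(seed = as.integer(seed), simulate = simulate,
                 counts_file = counts_file, genemap_file = genemap_file,
                 samples_file = samples_file, counts_format = counts_format,
                 min_cpm = min_cpm, min_fraction = min_fraction,
                 pseudocount = pseudocount, pair_strategy = pair_strategy,
                 z_threshold = z_threshold,
                 effect_floor_log2 = effect_floor_log2,
                 min_genes = min_genes, n_components = n_components,
                 weighting = weighting),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulate`
#' block holds [simulation_config()] arguments (its `design` block may give
#' `n_per_ploidy`, `sites`, `cohorts`, `dams` for [default_design()], or be
#' a list of explicit cells).
#'
#' @param path YAML file.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) {
    sim_args <- raw$simulate
    if (!is.null(sim_args$design)) {
      d <- sim_args$design
      sim_args$design <- if (is.data.frame(d)) d
        else if (!is.null(d$n_per_ploidy) || !is.null(d$sites))
          do.call(default_design, d)
        else do.call(rbind, lapply(d, as.data.frame))
    }
    if (!is.null(sim_args$aneuploidy_events))
      sim_args$aneuploidy_events <-
        do.call(rbind, lapply(sim_args$aneuploidy_events, as.data.frame))
    raw$simulate <- do.call(simulation_config, sim_args)
  }
  do.call(run_config, raw)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full screening pipeline
#'
#' Executes the stages simulate (optional) -> filter -> normalize -> pairs
#' -> aneuploidy screen -> transcriptomic shift, writing every stage output
#' and a machine-readable manifest (parameters, seed, package version, MD5
#' checksums of inputs and outputs, defaults applied) to `outdir`. A rerun
#' with the same configuration and inputs reproduces every output file
#' byte-for-byte; the manifest records only content (relative paths and
#' checksums, no timestamps) so it is itself reproducible.
#'
#' @param config a [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the in-memory stage results (`counts`,
#'   `filtered`, `logcpm`, `genemap`, `samples`, `pairs`, `screen`,
#'   `shift`, `manifest`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    stop("config must be a run_config object or a YAML path")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  outputs <- character(0)
  inputs <- character(0)

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      cfg <- config$simulate
      cfg$seed <- config$seed
      simulate_dataset(cfg)
    })
    counts <- sim$counts
    genemap <- sim$genemap
    samples <- sim$samples
    files <- write_dataset(sim, outdir)
    outputs <- c(outputs, unname(files))
  } else {
    counts <- stage("read_counts",
                    read_counts(config$counts_file, config$counts_format))
    genemap <- stage("read_genemap", read_genemap(config$genemap_file))
    samples <- stage("read_samples", read_samples(config$samples_file))
    inputs <- c(config$counts_file, config$genemap_file, config$samples_file)
  }
  genemap <- stage("align_genemap", align_genemap(counts, genemap))

  filtered <- stage("filter",
                    filter_low_expression(counts, config$min_cpm,
                                          config$min_fraction))
  outputs <- c(outputs,
               .write_tsv(data.frame(gene_id = rownames(filtered), filtered,
                                     check.names = FALSE),
                          file.path(outdir, "filtered_counts.tsv")))

  logcpm <- stage("normalize", log_cpm(filtered, config$pseudocount))
  outputs <- c(outputs,
               .write_tsv(data.frame(gene_id = rownames(logcpm),
                                     round(logcpm, 6), check.names = FALSE),
                          file.path(outdir, "logcpm.tsv")))

  pairs <- stage("pairs",
                 match_pairs(samples, config$pair_strategy,
                             seed = config$seed))
  outputs <- c(outputs, .write_tsv(pairs, file.path(outdir, "pairs.tsv")))

  screen <- stage("aneuploidy",
                  screen_all_pairs(logcpm, genemap, pairs,
                                   config$z_threshold,
                                   config$effect_floor_log2,
                                   config$min_genes))
  outputs <- c(outputs, .write_tsv(screen,
                                   file.path(outdir, "aneuploidy.tsv")))
  outputs <- c(outputs,
               .write_tsv(attr(screen, "pair_summary"),
                          file.path(outdir, "aneuploidy_pair_summary.tsv")))

  shift <- stage("shift", {
    pca <- expression_pca(logcpm, config$n_components)
    transcriptomic_shift(pca, pairs, config$n_components, config$weighting)
  })
  outputs <- c(outputs, .write_tsv(shift, file.path(outdir, "shift.tsv")))
  outputs <- c(outputs,
               .write_tsv(shift_summary(shift),
                          file.path(outdir, "shift_summary.tsv")))

  params <- config
  params$simulate <- if (is.null(config$simulate)) NULL
                     else unclass(config$simulate)
  manifest <- list(
    package = "ploidyscreen",
    version = as.character(utils::packageVersion("ploidyscreen")),
    seed = config$seed,
    parameters = unclass(params),
    stages = c(if (!is.null(config$simulate)) "simulate",
               "filter", "normalize", "pairs", "aneuploidy", "shift"),
    inputs = if (length(inputs))
      as.list(stats::setNames(unname(tools::md5sum(inputs)),
                              basename(inputs))) else NULL,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(counts = counts, filtered = filtered, logcpm = logcpm,
                 genemap = genemap, samples = samples, pairs = pairs,
                 screen = screen, shift = shift, manifest = manifest))
}
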