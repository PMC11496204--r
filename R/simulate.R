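#' Replicate layout of a mixed-ploidy outplant experiment
#'
#' Builds the design table consumed by [simulation_config()]: one row per
#' (site, cohort, dam) cell with the number of diploid and triploid
#' individuals sampled from that cross at that site. The defaults reproduce
#' the layout of a two-site, two-hatchery, three-dam oyster outplant with
#' eight individuals sampled per cross per site (192 samples in total).
#'
#' @param n_per_ploidy integer, individuals sampled per ploidy in every cell.
#' @param sites,cohorts,dams character vectors of factor levels.
#' @return data.frame with columns `site`, `cohort`, `dam`, `n_diploid`,
#'   `n_triploid`.
#' @export
#' @examples
#' nrow(default_design())    # 12 cells
#' sum(default_design()$n_diploid)  # 96 diploids
default_design <- function(n_per_ploidy = 8,
                           sites = c("GrandIsle", "LUMCON"),
                           cohorts = c("AU", "LSU"),
                           dams = c("CL", "SL", "VB")) {
  cells <- expand.grid(site = sites, cohort = cohorts, dam = dams,
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$site, cells$cohort, cells$dam), , drop = FALSE]
  rownames(cells) <- NULL
  cells$n_diploid <- as.integer(n_per_ploidy)
  cells$n_triploid <- as.integer(n_per_ploidy)
  cells
}

#' Configuration for the mixed-ploidy count simulator
#'
#' Collects and validates every parameter of the generative model used by
#' [simulate_dataset()]. The model draws gene-level counts from a negative
#' binomial whose mean is proportional to library size times the gene's
#' relative expression, where relative expression is the product of a
#' log-normal baseline, the chromosome copy number of the sample (raised to
#' the dosage-compensation exponent), and multiplicative covariate effects.
#'
#' @param n_genes number of genes.
#' @param n_chromosomes number of chromosomes (default 10, the oyster
#'   karyotype).
#' @param chromosome_weights simplex vector of length `n_chromosomes`
#'   giving the fraction of genes on each chromosome; default uniform.
#'   Genes are apportioned deterministically (largest-remainder) so the
#'   realized per-chromosome gene counts match the weights as closely as
#'   an integer split allows.
#' @param design data.frame as returned by [default_design()].
#' @param baseline_log_mean,baseline_log_sd mean and sd of per-gene log
#'   (natural) baseline expression; genes are log-normal.
#' @param dispersion negative-binomial size parameter shared by all genes;
#'   larger is less overdispersed, `Inf` gives the Poisson limit.
#' @param lib_size_mean,lib_size_cv mean and coefficient of variation of
#'   log-normally distributed library sizes; `lib_size_cv = 0` fixes every
#'   library at `lib_size_mean`.
#' @param covariate_effect_sd sd (natural-log scale) of gene-wise
#'   multiplicative site/cohort/ploidy effects, shared within each factor
#'   level and applied to the `frac_affected_genes` subset.
#' @param frac_affected_genes fraction of genes carrying covariate effects.
#' @param ploidy_site_interaction_sd sd of an extra gene-wise effect applied
#'   to triploids at `interaction_site` only, so that ploidy effects can be
#'   made stronger at one site; default 0 (off).
#' @param interaction_site site level receiving the interaction effect;
#'   default the second level appearing in `design`.
#' @param dosage_compensation exponent on copy number: 1 is fully
#'   proportional dosage (default), 0 is complete compensation.
#' @param aneuploidy_events `NULL` or data.frame with columns `sample_id`,
#'   `chromosome_id`, `copy_number` (positive integers in 1..4) overriding
#'   the euploid karyotype of specific samples.
#' @param seed integer seed; the same configuration always yields the same
#'   dataset.
#' @return an object of class `simulation_config`.
#' @seealso [simulate_dataset()]
#' @export
simulation_config <- function(n_genes = 5000,
                              n_chromosomes = 10,
                              chromosome_weights = NULL,
                              design = default_design(),
                              baseline_log_mean = 3,
                              baseline_log_sd = 1.5,
                              dispersion = 10,
                              lib_size_mean = 1e6,
                              lib_size_cv = 0.2,
                              covariate_effect_sd = 0,
                              frac_affected_genes = 0.1,
                              ploidy_site_interaction_sd = 0,
                              interaction_site = NULL,
                              dosage_compensation = 1,
                              aneuploidy_events = NULL,
                              seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    stop("n_genes must be a positive integer")
  if (!is.numeric(n_chromosomes) || length(n_chromosomes) != 1 ||
      n_chromosomes < 1)
    stop("n_chromosomes must be a positive integer")
  n_genes <- as.integer(n_genes)
  n_chromosomes <- as.integer(n_chromosomes)
  if (is.null(chromosome_weights))
    chromosome_weights <- rep(1 / n_chromosomes, n_chromosomes)
  if (length(chromosome_weights) != n_chromosomes)
    stop("chromosome_weights must have length n_chromosomes")
  if (any(chromosome_weights < 0) ||
      abs(sum(chromosome_weights) - 1) > 1e-12)
    stop("chromosome_weights must be a simplex vector (nonnegative, summing to 1)")
  if (!is.data.frame(design) || nrow(design) == 0)
    stop("design must be a nonempty data.frame")
  needed <- c("site", "cohort", "dam", "n_diploid", "n_triploid")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols))
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(design$n_diploid < 0) || any(design$n_triploid < 0) ||
      sum(design$n_diploid) + sum(design$n_triploid) < 1)
    stop("design must request a positive total number of samples")
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion <= 0)
    stop("dispersion must be a positive real (Inf for the Poisson limit)")
  if (lib_size_mean <= 0) stop("lib_size_mean must be positive")
  if (lib_size_cv < 0) stop("lib_size_cv must be nonnegative")
  if (baseline_log_sd < 0) stop("baseline_log_sd must be nonnegative")
  if (covariate_effect_sd < 0) stop("covariate_effect_sd must be nonnegative")
  if (ploidy_site_interaction_sd < 0)
    stop("ploidy_site_interaction_sd must be nonnegative")
  if (frac_affected_genes < 0 || frac_affected_genes > 1)
    stop("frac_affected_genes must lie in [0, 1]")
  if (dosage_compensation < 0)
    stop("dosage_compensation must be nonnegative")
  if (!is.null(aneuploidy_events)) {
    ev <- as.data.frame(aneuploidy_events)
    ev_cols <- c("sample_id", "chromosome_id", "copy_number")
    if (!all(ev_cols %in% names(ev)))
      stop("aneuploidy_events needs columns: ", paste(ev_cols, collapse = ", "))
    if (any(ev$copy_number != as.integer(ev$copy_number)) ||
        any(ev$copy_number < 1) || any(ev$copy_number > 4))
      stop("aneuploidy_events copy_number values must be integers in 1..4")
    aneuploidy_events <- ev
  }
  if (is.null(interaction_site)) interaction_site <- unique(design$site)[
    min(2L, length(unique(design$site)))]
  structure(list(
    n_genes = n_genes,
    n_chromosomes = n_chromosomes,
    chromosome_weights = chromosome_weights,
    design = design,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    dispersion = dispersion,
    lib_size_mean = lib_size_mean,
    lib_size_cv = lib_size_cv,
    covariate_effect_sd = covariate_effect_sd,
    frac_affected_genes = frac_affected_genes,
    ploidy_site_interaction_sd = ploidy_site_interaction_sd,
    interaction_site = interaction_site,
    dosage_compensation = dosage_compensation,
    aneuploidy_events = aneuploidy_events,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# largest-remainder apportionment of n items over simplex weights
.apportion <- function(n, weights) {
  raw <- n * weights
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.build_sample_table <- function(design) {
  rows <- lapply(seq_len(nrow(design)), function(i) {
    cell <- design[i, ]
    mk <- function(ploidy, n) {
      if (n == 0) return(NULL)
      data.frame(
        sample_id = sprintf("%s_%s_%s_%s_%02d", cell$site, cell$cohort,
                            cell$dam, ploidy, seq_len(n)),
        ploidy = ploidy, site = cell$site, cohort = cell$cohort,
        dam = cell$dam, stringsAsFactors = FALSE)
    }
    rbind(mk("2n", cell$n_diploid), mk("3n", cell$n_triploid))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a mixed-ploidy RNA-seq count dataset
#'
#' Draws a gene-by-sample count matrix, gene-to-chromosome map, sample
#' metadata table, and the true per-sample karyotype under the generative
#' model described in [simulation_config()]. The count for gene g in sample
#' s is negative binomial with mean
#' \deqn{\mu_{gs} = L_s \frac{c_{k(g),s}^{\gamma}\, e_g\, m_{gs}}
#'   {\sum_{g'} c_{k(g'),s}^{\gamma}\, e_{g'}\, m_{g's}}}
#' where \eqn{L_s} is the library size, \eqn{c_{k,s}} the copy number of
#' chromosome k in sample s (2 for diploids, 3 for triploids, overridden by
#' planted aneuploidy events), \eqn{\gamma} the dosage-compensation
#' exponent, \eqn{e_g} the log-normal baseline, and \eqn{m_{gs}} the product
#' of multiplicative covariate effects. Because the mean is renormalized by
#' the sample total, whole-genome ploidy cancels: only chromosome-specific
#' copy-number deviations show up after library-size normalization, which is
#' exactly the signal the aneuploidy screen targets.
#'
#' @param config a [simulation_config()] object.
#' @return list of class `ploidy_sim` with elements
#'   \item{counts}{integer matrix, genes x samples, with dimnames}
#'   \item{genemap}{data.frame `gene_id`, `chromosome_id`}
#'   \item{samples}{data.frame `sample_id`, `ploidy`, `site`, `cohort`, `dam`}
#'   \item{karyotype}{integer matrix, samples x chromosomes: true copy numbers}
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(
#'   n_genes = 200, design = default_design(n_per_ploidy = 1), seed = 7))
#' dim(sim$counts)
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("config must be created by simulation_config()")
  withr::with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(config) {
  n_genes <- config$n_genes
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  per_chr <- .apportion(n_genes, config$chromosome_weights)
  genemap <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n_genes)),
    chromosome_id = rep(chroms, per_chr),
    stringsAsFactors = FALSE)

  samples <- .build_sample_table(config$design)
  n_samples <- nrow(samples)

  karyotype <- matrix(ifelse(samples$ploidy == "3n", 3L, 2L),
                      nrow = n_samples, ncol = config$n_chromosomes,
                      dimnames = list(samples$sample_id, chroms))
  if (!is.null(config$aneuploidy_events)) {
    ev <- config$aneuploidy_events
    bad_s <- setdiff(ev$sample_id, samples$sample_id)
    if (length(bad_s))
      stop("aneuploidy_events refers to unknown sample_id: ",
           paste(bad_s, collapse = ", "))
    bad_c <- setdiff(ev$chromosome_id, chroms)
    if (length(bad_c))
      stop("aneuploidy_events refers to unknown chromosome_id: ",
           paste(bad_c, collapse = ", "))
    karyotype[cbind(ev$sample_id, ev$chromosome_id)] <- as.integer(ev$copy_number)
  }

  e <- exp(stats::rnorm(n_genes, config$baseline_log_mean,
                        config$baseline_log_sd))

  # gene-wise multiplicative covariate effects, shared within factor level
  n_affected <- round(config$frac_affected_genes * n_genes)
  affected <- if (n_affected > 0) sort(sample.int(n_genes, n_affected))
              else integer(0)
  log_m <- matrix(0, n_genes, n_samples)
  if (config$covariate_effect_sd > 0 && length(affected)) {
    for (fac in c("site", "cohort", "ploidy")) {
      levs <- unique(samples[[fac]])
      eff <- matrix(0, n_genes, length(levs), dimnames = list(NULL, levs))
      for (lv in levs)
        eff[affected, lv] <- stats::rnorm(length(affected), 0,
                                          config$covariate_effect_sd)
      log_m <- log_m + eff[, samples[[fac]], drop = FALSE]
    }
  }
  if (config$ploidy_site_interaction_sd > 0 && length(affected)) {
    delta <- numeric(n_genes)
    delta[affected] <- stats::rnorm(length(affected), 0,
                                    config$ploidy_site_interaction_sd)
    hit <- samples$ploidy == "3n" & samples$site == config$interaction_site
    log_m[, hit] <- log_m[, hit] + delta
  }

  # relative expression: copy-number dosage x baseline x covariate effects
  cmat <- t(karyotype)[genemap$chromosome_id, , drop = FALSE]
  rel <- (cmat ^ config$dosage_compensation) * e * exp(log_m)
  rel <- sweep(rel, 2, colSums(rel), "/")

  lib <- if (config$lib_size_cv > 0) {
    sdlog <- sqrt(log(1 + config$lib_size_cv^2))
    stats::rlnorm(n_samples, log(config$lib_size_mean) - sdlog^2 / 2, sdlog)
  } else rep(config$lib_size_mean, n_samples)

  mu <- sweep(rel, 2, lib, "*")
  counts <- if (is.infinite(config$dispersion)) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
  }
  counts <- matrix(as.integer(counts), n_genes, n_samples,
                   dimnames = list(genemap$gene_id, samples$sample_id))

  structure(list(counts = counts, genemap = genemap, samples = samples,
                 karyotype = karyotype),
            class = "ploidy_sim")
}

#' Recover planted copy-number events from a karyotype truth matrix
#'
#' Inverts the event encoding of [simulate_dataset()]: every entry of the
#' truth matrix that deviates from the ploidy baseline (2 for diploids, 3
#' for triploids) is reported as one event row.
#'
#' @param karyotype samples x chromosomes integer matrix.
#' @param samples sample metadata table with `sample_id` and `ploidy`.
#' @return data.frame with columns `sample_id`, `chromosome_id`,
#'   `copy_number`; zero rows if the dataset is fully euploid.
#' @export
karyotype_events <- function(karyotype, samples) {
  baseline <- ifelse(samples$ploidy[match(rownames(karyotype),
                                          samples$sample_id)] == "3n", 3L, 2L)
  dev <- which(karyotype != baseline, arr.ind = TRUE)
  out <- data.frame(
    sample_id = rownames(karyotype)[dev[, 1]],
    chromosome_id = colnames(karyotype)[dev[, 2]],
    copy_number = as.integer(karyotype[dev]),
    stringsAsFactors = FALSE)
  out[order(out$sample_id, out$chromosome_id), , drop = FALSE]
}

#' Write a simulated dataset to plain-text files
#'
#' @param sim a `ploidy_sim` object.
#' @param dir output directory (created if absent).
#' @param format `"tsv"` or `"mtx"` for the count matrix.
#' @return invisibly, a named character vector of the files written.
#' @export
write_dataset <- function(sim, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_path <- file.path(dir, if (format == "tsv") "counts.tsv" else "counts.mtx")
  write_counts(sim$counts, counts_path, format = format)
  files <- c(counts = counts_path,
             genemap = file.path(dir, "genemap.tsv"),
             samples = file.path(dir, "samples.csv"),
             karyotype = file.path(dir, "karyotype.tsv"))
  write_genemap(sim$genemap, files[["genemap"]])
  write_samples(sim$samples, files[["samples"]])
  kdf <- data.frame(sample_id = rownames(sim$karyotype),
                    as.data.frame(sim$karyotype), check.names = FALSE)
  utils::write.table(kdf, files[["karyotype"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(files)
}
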