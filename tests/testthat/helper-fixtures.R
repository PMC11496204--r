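# shared fixture builders and independent oracles

# small deterministic count matrix with chromosome structure
toy_counts <- function(n_genes = 40, n_samples = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_samples, 50), n_genes, n_samples)
  })
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  storage.mode(m) <- "integer"
  m
}

toy_genemap <- function(gene_ids, n_chromosomes = 2) {
  data.frame(gene_id = gene_ids,
             chromosome_id = rep(sprintf("chr%d", seq_len(n_chromosomes)),
                                 length.out = length(gene_ids)),
             stringsAsFactors = FALSE)
}

# one diploid + one triploid sample with optional planted copy-number event
pair_config <- function(n_genes = 5000, seed = 1, copy_number = NULL,
                        event_chromosome = "chr1", dispersion = Inf,
                        lib_size_cv = 0, ...) {
  des <- default_design(n_per_ploidy = 1)[1, ]
  events <- if (!is.null(copy_number))
    data.frame(sample_id = "GrandIsle_AU_CL_3n_01",
               chromosome_id = event_chromosome,
               copy_number = copy_number, stringsAsFactors = FALSE)
  simulation_config(n_genes = n_genes, design = des, dispersion = dispersion,
                    lib_size_cv = lib_size_cv, aneuploidy_events = events,
                    seed = seed, ...)
}

# independent least-squares oracle: coarse grid scan followed by generic
# numeric minimization of the squared error; knows nothing of the
# closed-form normal equations
brute_force_ols <- function(x, y, half_width = 10, grid_points = 41) {
  sse <- function(p) sum((y - p[1] - p[2] * x)^2)
  as <- seq(-half_width, half_width, length.out = grid_points)
  bs <- seq(-half_width, half_width, length.out = grid_points)
  errs <- outer(as, bs, Vectorize(function(a, b) sse(c(a, b))))
  best <- arrayInd(which.min(errs), dim(errs))
  p <- c(as[best[1]], bs[best[2]])
  for (i in 1:3)  # restart Nelder-Mead to escape premature shrinkage
    p <- stats::optim(p, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))$par
  list(intercept = p[1], slope = p[2])
}
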