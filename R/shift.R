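#' Principal component analysis of a log-CPM matrix
#'
#' Gene-centered PCA over samples via singular value decomposition
#' (samples are observations, genes are variables). Variance fractions are
#' computed over the full spectrum; each retained component's loading
#' vector is oriented so that its largest-magnitude entry is positive,
#' making the sign deterministic.
#'
#' @param logcpm numeric matrix, genes x samples (e.g. from [log_cpm()]).
#' @param n_components number of components to retain (default 2); must not
#'   exceed `min(n_samples - 1, n_genes)`.
#' @return object of class `expression_pca`: list with `scores`
#'   (samples x components), `variance_fraction` (retained components),
#'   `all_variance_fraction`, `rotation` (gene loadings), `n_components`.
#' @export
expression_pca <- function(logcpm, n_components = 2) {
  if (ncol(logcpm) < 2) stop("PCA needs at least 2 samples")
  kmax <- min(ncol(logcpm) - 1, nrow(logcpm))
  if (n_components < 1 || n_components > kmax)
    stop("n_components must lie in 1..", kmax,
         " (min(n_samples - 1, n_genes))")
  pc <- stats::prcomp(t(logcpm), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot < .Machine$double.eps * nrow(logcpm))
    stop("expression matrix is constant: no variance to decompose")
  vf <- ev / tot
  keep <- seq_len(n_components)
  scores <- pc$x[, keep, drop = FALSE]
  rotation <- pc$rotation[, keep, drop = FALSE]
  for (j in keep) {
    v <- rotation[, j]
    if (v[which.max(abs(v))] < 0) {
      rotation[, j] <- -v
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores,
                 variance_fraction = vf[keep],
                 all_variance_fraction = vf,
                 rotation = rotation,
                 n_components = n_components),
            class = "expression_pca")
}

#' @export
print.expression_pca <- function(x, ...) {
  cat("Expression PCA:", nrow(x$scores), "samples,",
      x$n_components, "components retained\n")
  cat("variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Transcriptomic shift between matched diploid/triploid samples
#'
#' Euclidean distance in variance-weighted principal-component space
#' between the two members of each matched pair:
#' \deqn{d = \sqrt{\sum_{i \le k} \big(w_i\,(s_i^{3n} - s_i^{2n})\big)^2}}
#' where \eqn{s_i} are PC scores and the default weight \eqn{w_i} is
#' component i's variance fraction, so displacement along a dominant axis
#' counts for more. Weighting `"sqrt"` uses the square root of the
#' fraction (equivalent to weighting squared terms by the fraction) and
#' `"none"` gives the plain Euclidean distance.
#'
#' @param pca an [expression_pca()] result containing every pair member.
#' @param pairs data.frame from [match_pairs()].
#' @param n_components components used (default 2, i.e. PC1 and PC2); must
#'   not exceed those retained in `pca`.
#' @param weighting `"fraction"` (default), `"sqrt"`, or `"none"`.
#' @return data.frame: `pair_id`, `diploid_id`, `triploid_id`, `site`,
#'   `cohort`, `dam`, `distance`; attributes `weighting` and
#'   `components_used`.
#' @seealso [shift_summary()] for per-site/cohort medians.
#' @export
transcriptomic_shift <- function(pca, pairs, n_components = 2,
                                 weighting = c("fraction", "sqrt", "none")) {
  weighting <- match.arg(weighting)
  if (!inherits(pca, "expression_pca"))
    stop("pca must be an expression_pca object")
  if (n_components > pca$n_components)
    stop("n_components exceeds the ", pca$n_components,
         " components retained in the PCA")
  ids <- c(pairs$diploid_id, pairs$triploid_id)
  missing_ids <- setdiff(ids, rownames(pca$scores))
  if (length(missing_ids))
    stop("sample(s) missing from PCA scores: ",
         paste(missing_ids, collapse = ", "))
  k <- seq_len(n_components)
  w <- switch(weighting,
              fraction = pca$variance_fraction[k],
              sqrt = sqrt(pca$variance_fraction[k]),
              none = rep(1, n_components))
  delta <- pca$scores[pairs$triploid_id, k, drop = FALSE] -
           pca$scores[pairs$diploid_id, k, drop = FALSE]
  dist <- sqrt(rowSums(sweep(delta, 2, w, "*")^2))
  out <- data.frame(pair_id = pairs$pair_id,
                    diploid_id = pairs$diploid_id,
                    triploid_id = pairs$triploid_id,
                    site = pairs$site, cohort = pairs$cohort,
                    dam = pairs$dam, distance = unname(dist),
                    stringsAsFactors = FALSE)
  attr(out, "weighting") <- weighting
  attr(out, "components_used") <- n_components
  out
}

#' Summarize transcriptomic shifts by site and cohort
#'
#' @param shifts data.frame from [transcriptomic_shift()].
#' @return data.frame with one row per site x cohort: `n`, `median`, `q25`,
#'   `q75`, `iqr` of the pair distances.
#' @export
shift_summary <- function(shifts) {
  groups <- split(shifts$distance,
                  list(site = shifts$site, cohort = shifts$cohort),
                  drop = TRUE)
  keys <- do.call(rbind, strsplit(names(groups), ".", fixed = TRUE))
  out <- data.frame(
    site = keys[, 1], cohort = keys[, 2],
    n = vapply(groups, length, integer(1)),
    median = vapply(groups, stats::median, numeric(1)),
    q25 = vapply(groups, stats::quantile, numeric(1), probs = 0.25,
                 names = FALSE),
    q75 = vapply(groups, stats::quantile, numeric(1), probs = 0.75,
                 names = FALSE),
    stringsAsFactors = FALSE)
  out$iqr <- out$q75 - out$q25
  rownames(out) <- NULL
  out[order(out$site, out$cohort), , drop = FALSE]
}

#' Box plot of pair shifts by site, colored by cohort
#'
#' Minimal plotting utility mirroring the usual presentation of matched
#' pair distances: one box per site, filled by cohort.
#'
#' @param shifts data.frame from [transcriptomic_shift()].
#' @return a ggplot object.
#' @export
plot_shift <- function(shifts) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_shift requires the ggplot2 package")
  ggplot2::ggplot(shifts,
                  ggplot2::aes(x = site, y = distance, fill = cohort)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "outplant site",
                  y = "transcriptomic shift (weighted PC distance)") +
    ggplot2::theme_minimal()
}
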