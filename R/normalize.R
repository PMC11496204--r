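.validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and sample identifiers as dimnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene id: ",
         rownames(counts)[anyDuplicated(rownames(counts))])
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample id: ",
         colnames(counts)[anyDuplicated(colnames(counts))])
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (ncol(counts) < 2) stop("counts needs at least 2 samples")
  if (nrow(counts) < 1) stop("counts needs at least 1 gene")
  invisible(counts)
}

#' Counts per million
#'
#' Scales each sample's counts by its library size (column sum) times 1e6,
#' so every column of the result sums to exactly one million. This removes
#' library-size differences and, with it, any whole-genome dosage
#' difference between ploidies: a uniform tripling of all transcripts is
#' invisible after CPM normalization.
#'
#' @param counts nonnegative numeric matrix, genes x samples, with gene and
#'   sample identifiers as dimnames.
#' @return numeric matrix of the same shape; columns sum to 1e6.
#' @export
#' @examples
#' m <- matrix(c(10, 990, 5, 95), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' cpm(m)[, "a"]   # 10000 990000
cpm <- function(counts) {
  .validate_counts(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  sweep(counts, 2, lib, "/") * 1e6
}

#' Log2 counts per million
#'
#' Computes `log2(CPM + pseudocount)`. The default pseudocount of 1 maps a
#' zero count to exactly 0 on the log scale.
#'
#' @inheritParams cpm
#' @param pseudocount positive real added before the log.
#' @return matrix of log2(CPM + pseudocount) values with attributes
#'   `pseudocount` and `log_base` (2).
#' @export
log_cpm <- function(counts, pseudocount = 1) {
  cpm_to_log(cpm(counts), pseudocount = pseudocount)
}

#' Log-transform an existing CPM matrix
#'
#' @param cpm_matrix matrix of CPM values (e.g. from [cpm()]).
#' @inheritParams log_cpm
#' @return same contract as [log_cpm()].
#' @export
cpm_to_log <- function(cpm_matrix, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a positive real")
  out <- log2(cpm_matrix + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "log_base") <- 2
  out
}

#' Filter lowly expressed genes
#'
#' Retains a gene only if its CPM is at least `min_cpm` in at least
#' `ceiling(min_fraction * n_samples)` samples (the keep-if-expressed rule;
#' at the boundary a gene with CPM exactly `min_cpm` in exactly the
#' required fraction of samples is kept). Gene order is preserved.
#'
#' @inheritParams cpm
#' @param min_cpm CPM threshold (default 5).
#' @param min_fraction minimum fraction of samples meeting the threshold
#'   (default 0.8).
#' @return the count matrix restricted to retained genes.
#' @export
filter_low_expression <- function(counts, min_cpm = 5, min_fraction = 0.8) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  cm <- cpm(counts)
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(cm >= min_cpm) >= need
  if (!any(keep))
    stop("all genes removed by the low-expression filter; ",
         "review min_cpm (", min_cpm, ") and min_fraction (", min_fraction, ")")
  counts[keep, , drop = FALSE]
}
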