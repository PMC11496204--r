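.validate_samples <- function(samples) {
  needed <- c("sample_id", "ploidy", "site", "cohort", "dam")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols))
    stop("sample table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id: ",
         samples$sample_id[anyDuplicated(samples$sample_id)])
  bad <- setdiff(unique(samples$ploidy), c("2n", "3n"))
  if (length(bad))
    stop("ploidy must be '2n' or '3n'; found: ", paste(bad, collapse = ", "))
  invisible(samples)
}

#' Match diploid and triploid samples on site, cohort, and dam
#'
#' Within every (site, cohort, dam) cell, diploids and triploids are paired
#' one-to-one up to `min(n_2n, n_3n)` pairs. The `ordered` strategy pairs
#' samples by lexicographic sample id (deterministic); `random` permutes
#' each ploidy's samples within the cell under `seed` before pairing, for
#' sensitivity analysis. Cells lacking one ploidy contribute no pairs and
#' raise a warning; samples left without a partner are reported in the
#' `unmatched` attribute, never silently dropped.
#'
#' @param samples data.frame with columns `sample_id`, `ploidy` (`2n`/`3n`),
#'   `site`, `cohort`, `dam`.
#' @param strategy `"ordered"` (default) or `"random"`.
#' @param seed integer seed for the random strategy.
#' @return data.frame with columns `pair_id`, `diploid_id`, `triploid_id`,
#'   `site`, `cohort`, `dam`; attribute `unmatched` holds the leftover
#'   sample table rows.
#' @export
#' @examples
#' tab <- data.frame(sample_id = c("a", "b", "x", "y"),
#'                   ploidy = c("2n", "2n", "3n", "3n"),
#'                   site = "S", cohort = "C", dam = "D")
#' match_pairs(tab)
match_pairs <- function(samples, strategy = c("ordered", "random"),
                        seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.data.frame(samples) || nrow(samples) == 0)
    stop("sample table must be a nonempty data.frame")
  .validate_samples(samples)
  build <- function() {
    key <- paste(samples$site, samples$cohort, samples$dam, sep = "\r")
    cells <- unique(samples[order(samples$site, samples$cohort, samples$dam),
                            c("site", "cohort", "dam")])
    pair_rows <- list()
    unmatched <- list()
    for (i in seq_len(nrow(cells))) {
      cell <- cells[i, ]
      in_cell <- key == paste(cell$site, cell$cohort, cell$dam, sep = "\r")
      d <- sort(samples$sample_id[in_cell & samples$ploidy == "2n"])
      t3 <- sort(samples$sample_id[in_cell & samples$ploidy == "3n"])
      if (length(d) == 0 || length(t3) == 0) {
        warning("cell site=", cell$site, " cohort=", cell$cohort,
                " dam=", cell$dam, " has no ",
                if (length(d) == 0) "diploid" else "triploid",
                " samples; skipped", call. = FALSE)
      }
      if (strategy == "random") {
        d <- sample(d)
        t3 <- sample(t3)
      }
      n <- min(length(d), length(t3))
      if (n > 0)
        pair_rows[[length(pair_rows) + 1]] <- data.frame(
          diploid_id = d[seq_len(n)], triploid_id = t3[seq_len(n)],
          site = cell$site, cohort = cell$cohort, dam = cell$dam,
          stringsAsFactors = FALSE)
      left <- c(utils::tail(d, length(d) - n), utils::tail(t3, length(t3) - n))
      if (length(left))
        unmatched[[length(unmatched) + 1]] <-
          samples[samples$sample_id %in% left, , drop = FALSE]
    }
    pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
      data.frame(diploid_id = character(), triploid_id = character(),
                 site = character(), cohort = character(),
                 dam = character(), stringsAsFactors = FALSE)
    rownames(pairs) <- NULL
    if (nrow(pairs))
      pairs <- cbind(pair_id = sprintf("pair%03d", seq_len(nrow(pairs))),
                     pairs, stringsAsFactors = FALSE)
    else pairs <- cbind(pair_id = character(), pairs)
    un <- if (length(unmatched)) do.call(rbind, unmatched) else
      samples[0, , drop = FALSE]
    rownames(un) <- NULL
    if (nrow(un))
      message(nrow(un), " sample(s) left unmatched (see attr 'unmatched')")
    attr(pairs, "unmatched") <- un
    pairs
  }
  if (strategy == "random" && !is.null(seed))
    withr::with_seed(as.integer(seed), build())
  else build()
}
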