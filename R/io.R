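.check_count_values <- function(m, what = "counts") {
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(what, " must be nonnegative integers; first offending entry at gene '",
         rownames(m)[bad[1, 1]], "', sample '", colnames(m)[bad[1, 2]],
         "' (value ", m[bad[1, 1], bad[1, 2]], ")")
  }
  invisible(m)
}

.mtx_sidecars <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  c(genes = paste0(stem, ".genes.txt"), samples = paste0(stem, ".samples.txt"))
}

#' Read a gene-by-sample count matrix
#'
#' Supports tab-separated text (first column = gene id, header row = sample
#' ids) and MatrixMarket coordinate format. A MatrixMarket file
#' `x.mtx` expects its row and column names in `x.genes.txt` and
#' `x.samples.txt`, one id per line (the layout [write_counts()] emits).
#' Implicit zeros in the sparse format are materialized, so both formats
#' round-trip to the same dense matrix. Duplicated identifiers, negative
#' values and non-integer values are rejected with the offending location.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"`, or `"mtx"`.
#' @return integer matrix, genes x samples, with dimnames.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- gene_ids
  } else {
    side <- .mtx_sidecars(path)
    if (!all(file.exists(side)))
      stop("MatrixMarket sidecar file(s) missing: ",
           paste(side[!file.exists(side)], collapse = ", "))
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(side[["genes"]])
    colnames(m) <- readLines(side[["samples"]])
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicated gene id in ", path, ": ",
         rownames(m)[anyDuplicated(rownames(m))])
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample id in ", path, ": ",
         colnames(m)[anyDuplicated(colnames(m))])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  .check_count_values(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix
#'
#' @param counts integer matrix with dimnames.
#' @param path output file; for `"mtx"`, two sidecar files with gene and
#'   sample ids are written next to it.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @return invisibly, `path`.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    side <- .mtx_sidecars(path)
    writeLines(rownames(counts), side[["genes"]])
    writeLines(colnames(counts), side[["samples"]])
  }
  invisible(path)
}

#' Read a gene-to-chromosome map
#'
#' Two-column tab-separated file with header `gene_id`, `chromosome_id`.
#' Chromosome identifiers are opaque strings: no naming scheme or ordering
#' is assumed.
#'
#' @param path input TSV.
#' @return data.frame `gene_id`, `chromosome_id`.
#' @export
read_genemap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("gene_id", "chromosome_id"), names(df))
  if (length(missing_cols))
    stop("gene map is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in gene map: ",
         df$gene_id[anyDuplicated(df$gene_id)])
  df[, c("gene_id", "chromosome_id")]
}

#' @rdname read_genemap
#' @param genemap data.frame `gene_id`, `chromosome_id`.
#' @export
write_genemap <- function(genemap, path) {
  utils::write.table(genemap[, c("gene_id", "chromosome_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Comma-separated file with columns `sample_id`, `ploidy` (`2n`/`3n`),
#' `site`, `cohort`, `dam`.
#'
#' @param path input CSV.
#' @return validated data.frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_samples(df)
  df
}

#' @rdname read_samples
#' @param samples sample metadata data.frame.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pair table written by the pipeline
#'
#' @param path TSV with columns `pair_id`, `diploid_id`, `triploid_id`,
#'   `site`, `cohort`, `dam`.
#' @return data.frame.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("pair_id", "diploid_id", "triploid_id", "site", "cohort", "dam")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("pair table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Derive a gene-to-chromosome map from a GFF3 file
#'
#' Extracts `gene`-type features and maps their `ID` (or `Name` when `ID`
#' is absent) attribute to the sequence (chromosome) they lie on. Parsing
#' is delegated to `rtracklayer::import`.
#'
#' @param path GFF3 file.
#' @param feature_type feature type to keep (default `"gene"`).
#' @return data.frame `gene_id`, `chromosome_id`.
#' @export
genemap_from_gff <- function(path, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("genemap_from_gff requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path))
  gr <- gr[gr$type == feature_type, , drop = FALSE]
  ids <- as.character(gr$ID)
  if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
  if (anyDuplicated(ids))
    stop("duplicated gene_id in GFF: ", ids[anyDuplicated(ids)])
  data.frame(gene_id = ids,
             chromosome_id = as.character(gr$seqnames),
             stringsAsFactors = FALSE)
}

#' Restrict a gene map to the genes of a count matrix
#'
#' Genes present in the matrix but absent from the map are reported via a
#' message (they remain usable for PCA/shift but are excluded from
#' chromosome-level analyses); map entries for genes not in the matrix are
#' dropped silently.
#'
#' @param counts count (or log-CPM) matrix with gene ids as rownames.
#' @param genemap data.frame `gene_id`, `chromosome_id`.
#' @return the gene map restricted to genes of `counts`; attribute
#'   `n_unmapped` holds the number of matrix genes without a map entry.
#' @export
align_genemap <- function(counts, genemap) {
  unmapped <- setdiff(rownames(counts), genemap$gene_id)
  if (length(unmapped))
    message(length(unmapped),
            " gene(s) in the matrix have no chromosome assignment; ",
            "excluded from chromosome-level analyses")
  out <- genemap[genemap$gene_id %in% rownames(counts), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- length(unmapped)
  out
}
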