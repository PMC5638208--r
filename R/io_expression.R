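#' Read / write an expression matrix TSV
#'
#' Genes x samples, header row of sample ids, first column gene ids.
#' Missing values are either imputed with the row median
#' (\code{na = "impute"}) or rejected (\code{na = "error"}).
#'
#' @param path file path.
#' @param na missing-value policy: \code{"impute"} (row median) or
#'   \code{"error"}.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, na = c("impute", "error")) {
  na <- match.arg(na)
  .check(file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  .check(ncol(tab) >= 2L, "expected gene column + >= 1 sample column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  .check(!anyDuplicated(rownames(m)), "duplicate gene ids in %s", path)
  if (anyNA(m)) {
    if (na == "error") .fail("missing values in %s", path)
    n_imputed <- sum(is.na(m))
    med <- apply(m, 1L, stats::median, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- med[idx[, 1L]]
    .log("imputed %d missing value(s) with row medians", n_imputed)
    .check(!anyNA(m), "rows with all values missing in %s", path)
  }
  m
}

#' @rdname read_expression
#' @param x matrix to write.
#' @param gene_col name for the gene-id column (default "gene").
#' @export
write_expression <- function(x, path, gene_col = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[[1]] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene signature TSV (gene, statistic)
#'
#' @param path file path.
#' @return named numeric vector of per-gene statistics.
#' @export
read_signature <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check(ncol(tab) >= 2L, "expected columns (gene, statistic) in %s", path)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' @rdname read_signature
#' @param x named numeric vector.
#' @export
write_signature <- function(x, path) {
  utils::write.table(data.frame(gene = names(x), statistic = unname(x)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' TSV with columns sample, perturbation, replicate_group, plate.
#'
#' @param path file path.
#' @return data.frame keyed by sample.
#' @export
read_sample_metadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "perturbation", "replicate_group", "plate")
  .check(all(need %in% colnames(tab)),
         "metadata must have columns: %s", paste(need, collapse = ", "))
  .check(!anyDuplicated(tab$sample), "duplicate sample ids in %s", path)
  tab
}

#' Collapse probe-level rows to one row per gene
#'
#' Among the probes mapping to a gene, the probe with the largest median
#' absolute deviation (MAD) across samples is kept; MAD ties are broken by
#' the lexicographically smallest probe id. Unmapped probes are dropped with
#' a logged count.
#'
#' @param x probes x samples matrix (probe rownames).
#' @param probe_to_gene named character vector: probe id -> gene id.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(x, probe_to_gene) {
  .check(is.matrix(x) && !is.null(rownames(x)), "x must have probe rownames")
  mapped <- rownames(x) %in% names(probe_to_gene)
  if (any(!mapped))
    .log("dropping %d unmapped probe(s)", sum(!mapped))
  x <- x[mapped, , drop = FALSE]
  .check(nrow(x) > 0L, "no probes map to genes")
  gene <- probe_to_gene[rownames(x)]
  mads <- apply(x, 1L, stats::mad)
  ord <- order(gene, -mads, rownames(x))  # per gene: max MAD, then probe id
  keep <- ord[!duplicated(gene[ord])]
  out <- x[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out[order(rownames(out)), , drop = FALSE]
}
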