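#' Read / write expression matrices as TSV
#'
#' The on-disk dialect is a tab-separated table whose first column `gene_id`
#' holds gene identifiers and whose remaining columns are samples, values on
#' the log2 scale.
#'
#' @param x genes x samples matrix or SummarizedExperiment.
#' @param path file path.
#' @return `readExpressionTsv` returns a genes x samples numeric matrix;
#'   `writeExpressionTsv` returns `path` invisibly.
#' @export
writeExpressionTsv <- function(x, path) {
  m <- .asExprMatrix(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTsv
#' @export
readExpressionTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
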