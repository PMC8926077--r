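# Tab-separated readers/writers for expression matrices and sample metadata.

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The expression file must have a first column of gene ids followed by one
#' numeric column per sample; the metadata file must have columns
#' \code{sample_id}, \code{condition}, \code{batch}, \code{age}, \code{sex}
#' (extra columns are kept).
#'
#' @param exprFile path to the expression TSV.
#' @param metaFile optional path to the metadata TSV.
#' @return An \linkS4class{ExpressionDataset}.
#' @export
readExpressionTSV <- function(exprFile, metaFile = NULL) {
  tab <- read.delim(exprFile, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  meta <- NULL
  if (!is.null(metaFile)) {
    meta <- read.delim(metaFile, check.names = FALSE,
                       stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(meta))
      stop("metadata file needs a sample_id column")
    rownames(meta) <- meta$sample_id
    meta <- meta[colnames(values), setdiff(names(meta), "sample_id"),
                 drop = FALSE]
  }
  ExpressionDataset(values, meta)
}

#' Write an ExpressionDataset to TSV
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param exprFile path for the expression TSV (first column \code{gene_id}).
#' @param metaFile optional path for the metadata TSV.
#' @return Invisibly, \code{exprFile}.
#' @export
writeExpressionTSV <- function(ds, exprFile, metaFile = NULL) {
  x <- exprMatrix(ds)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  .writeTSV(df, exprFile)
  if (!is.null(metaFile)) {
    cd <- as.data.frame(SummarizedExperiment::colData(ds))
    md <- data.frame(sample_id = colnames(x), cd, check.names = FALSE)
    .writeTSV(md, metaFile)
  }
  invisible(exprFile)
}

#' Read a probe-to-gene map from TSV
#'
#' @param path TSV with columns \code{probe_id} and \code{gene_id}.
#' @return Named character vector mapping probe ids to gene ids.
#' @export
readProbeMapTSV <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(tab)))
    stop("probe map needs columns probe_id and gene_id")
  setNames(as.character(tab$gene_id), as.character(tab$probe_id))
}
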