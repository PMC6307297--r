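# Transcript-level fpkm matrix with (tissue, stage) sample metadata.

#' Construct an expression matrix
#'
#' @param values numeric matrix, rows = transcript ids (rownames required),
#'   columns = samples named `tissue_stage` (e.g. `heart_E10.5`).
#' @param samples optional data.frame with columns `sample`, `tissue`,
#'   `stage`; derived from column names when omitted (tissue = text before the
#'   first underscore, stage = the rest).
#' @return object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples = NULL) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)))
  if (any(values < 0)) stop("fpkm values must be non-negative")
  if (is.null(samples)) {
    cn <- colnames(values)
    tissue <- sub("_.*$", "", cn)
    stage <- sub("^[^_]+_", "", cn)
    samples <- data.frame(sample = cn, tissue = tissue, stage = stage,
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(samples$sample == colnames(values)))
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d transcripts x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$tissue), collapse = ", ")))
  invisible(x)
}

#' Write an expression matrix as TSV
#' @param mat an [expr_matrix()].
#' @param path output path. First column `transcript_id`, then one column per
#'   sample named `tissue_stage`.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(transcript_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read an expression matrix from TSV
#' @param path TSV path as written by [write_expression_tsv()].
#' @return an [expr_matrix()].
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  expr_matrix(v)
}

# fpkm sub-matrix for one tissue (all its samples); missing transcripts are
# fpkm 0 everywhere, reported once via message().
tissue_values <- function(mat, ids, tissue) {
  cols <- mat$samples$sample[mat$samples$tissue == tissue]
  if (length(cols) == 0)
    stop("configuration error: tissue '", tissue, "' absent from expression matrix")
  miss <- setdiff(ids, rownames(mat$values))
  if (length(miss) > 0)
    message(length(miss), " transcript(s) absent from expression matrix; treated as fpkm 0")
  out <- matrix(0, nrow = length(ids), ncol = length(cols),
                dimnames = list(ids, cols))
  present <- intersect(ids, rownames(mat$values))
  out[present, ] <- mat$values[present, cols, drop = FALSE]
  out
}
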