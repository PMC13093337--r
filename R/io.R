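#' Read / write expression matrices with sample metadata
#'
#' CSV layout: the expression file has transcripts as rows (first column =
#' transcript name) and samples as columns; the metadata file has columns
#' sample_id, group, region, slice, sex.
#'
#' @param values expression matrix (transcripts x samples).
#' @param meta sample metadata data.frame.
#' @param values_path,meta_path file paths.
#' @return `read_expression_csv` returns `list(values, meta)`.
#' @export
write_expression_csv <- function(values, meta, values_path, meta_path) {
  df <- data.frame(transcript = rownames(values), values,
                   check.names = FALSE)
  write.csv(df, values_path, row.names = FALSE)
  write.csv(meta, meta_path, row.names = FALSE)
  invisible(values_path)
}

#' @rdname write_expression_csv
#' @export
read_expression_csv <- function(values_path, meta_path) {
  df <- read.csv(values_path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  meta <- read.csv(meta_path)
  if (!identical(colnames(values), as.character(meta$sample_id)))
    stop("metadata sample_id does not match expression columns")
  list(values = values, meta = meta)
}
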