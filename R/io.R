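#' Read and write pipeline tables as schema-versioned delimited text
#'
#' All tabular interchange in the package uses tab-separated text with a
#' single comment header line recording the schema name and version, so
#' files are auditable with standard tools and stable across releases.
#'
#' @param x A data frame.
#' @param path File path.
#' @param schema Short schema name written into the header.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_pipeline_table <- function(x, path, schema = "table") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hearburden-schema v1 %s", schema), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_pipeline_table
#' @export
read_pipeline_table <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  tibble::as_tibble(utils::read.delim(path, sep = "\t", skip = skip,
                                      stringsAsFactors = FALSE))
}
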