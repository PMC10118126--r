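#' Read and write the package's plain-text interchange formats
#'
#' Expression matrices travel as TSV with row ids in the first column
#' (structures or cell types as rows, genes as columns); gene sets as GMT
#' (set id, description, then tab-separated members); gene-disease tables as
#' long-format TSV.
#'
#' @param path file path.
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_matrix_tsv
#' @param m numeric matrix with dimnames.
#' @param id_name header for the row-id column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path file path.
#' @return named list of character vectors; the `description` attribute
#'   carries the second GMT column (used here for the GBD class label).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  desc <- vapply(parts, `[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  names(desc) <- ids
  attr(sets, "description") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  desc <- description %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
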