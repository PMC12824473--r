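#' Write a table as TSV with `#`-prefixed metadata header lines
#'
#' @param df data frame to write.
#' @param path output path.
#' @param meta named character/numeric vector written as `# key: value`
#'   lines before the header row.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()] (comment lines skipped)
#' @param path input path.
#' @return data frame.
#' @export
read_tsv_meta <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a tidy viability table as CSV
#' @param viability data frame (`cell_line`, `replicate`,
#'   `activity_mbq_per_ml`, `fraction` or `readout`).
#' @param path output path.
#' @export
write_viability_csv <- function(viability, path) {
  write.csv(viability, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy viability CSV
#' @param path input path.
#' @return data frame.
#' @export
read_viability_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a genes x samples expression matrix as TSV
#' @param mat matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples expression TSV
#' @param path input path (first column = gene identifiers).
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list: set name -> character vector of genes.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list: set name -> character vector of genes.
#' @param path output path.
#' @param description description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  stop_if(is.null(names(sets)), "sets must be a named list")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
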