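# Readers and writers for the pipeline's file formats: genotype dosage
# CSV/TSV or PLINK .raw, phenotype CSV, and labelled correlation matrices.

#' Read a genotype dosage table
#'
#' Accepts either a delimited table (first column = subject id, remaining
#' columns = per-SNP minor-allele dosages) or the PLINK `.raw` dialect
#' (`FID IID PAT MAT SEX PHENOTYPE` then `SNP_allele` columns, whitespace
#' separated). For `.raw` input the counted-allele suffix is stripped from
#' the SNP names and `IID` becomes `subject_id`.
#'
#' @param path File path.
#' @return A tibble with `subject_id` then one numeric column per SNP.
#' @export
read_genotypes <- function(path) {
  header <- strsplit(readLines(path, n = 1), "[,\t ]+")[[1]]
  plink <- length(header) >= 6 &&
    all(header[1:6] == c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  if (plink) {
    d <- readr::read_table(path, show_col_types = FALSE)
    snps <- names(d)[-(1:6)]
    out <- d[, c("IID", snps)]
    names(out) <- c("subject_id", sub("_[ACGT0-9]+$", "", snps))
    out$subject_id <- as.character(out$subject_id)
  } else {
    out <- readr::read_delim(path, show_col_types = FALSE,
                             delim = if (grepl("\t", readLines(path, n = 1))) "\t" else ",")
    names(out)[1] <- "subject_id"
    out$subject_id <- as.character(out$subject_id)
  }
  bad <- names(out)[-1][!map_lgl(out[-1], is.numeric)]
  if (length(bad) > 0)
    abort(sprintf("non-numeric dosage columns: %s", paste(bad, collapse = ", ")))
  out
}

#' Read a phenotype/covariate table
#'
#' A CSV whose first column is the subject id.
#'
#' @param path File path.
#' @return A tibble with `subject_id` first.
#' @export
read_phenotypes <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  names(d)[1] <- "subject_id"
  d$subject_id <- as.character(d$subject_id)
  d
}

#' Read / write a labelled correlation or covariance matrix as CSV
#'
#' The CSV has a header row and an index column with the variable labels.
#' An optional `n` attribute (sample size) travels in a `# n=<int>` comment
#' line written above the header.
#'
#' @param path File path.
#' @return `read_corr_matrix()`: the labelled matrix, with attribute `n` if
#'   the file carries one.
#' @export
read_corr_matrix <- function(path) {
  lines <- readLines(path)
  n <- NULL
  if (grepl("^# *n *=", lines[1])) {
    n <- as.integer(sub("^# *n *= *", "", lines[1]))
    lines <- lines[-1]
  }
  d <- utils::read.csv(text = paste(lines, collapse = "\n"), row.names = 1,
                       check.names = FALSE)
  m <- as.matrix(d)
  check_square_named(m, basename(path))
  if (!is.null(n)) attr(m, "n") <- n
  m
}

#' @rdname read_corr_matrix
#' @param m Labelled square matrix (attribute `n` is preserved).
#' @export
write_corr_matrix <- function(m, path) {
  check_square_named(m, "m")
  con <- file(path, "w")
  on.exit(close(con))
  n <- attr(m, "n")
  if (!is.null(n)) writeLines(sprintf("# n=%d", as.integer(n)), con)
  utils::write.csv(as.data.frame(m), con)
  invisible(path)
}
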