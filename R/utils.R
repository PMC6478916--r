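# Shared helpers: TSV conventions, validation, amino-acid alphabet.

# All tables are tab-separated UTF-8 with a header row; '.' marks missing.
NA_TOKEN <- "."

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a tab-separated table
#'
#' Reads a TSV with a header row, treating `"."` as missing. Extra columns
#' beyond those a caller requires are kept and ignored downstream.
#'
#' @param path Path to a TSV file.
#' @param required Character vector of column names that must be present.
#' @return A `data.frame`.
#' @export
read_tsv <- function(path, required = character()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = NA_TOKEN, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("format error in '%s': missing column(s) %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  # columns whose every non-missing entry parses as a number become numeric;
  # everything else (incl. single-letter amino acids) stays character
  for (nm in names(df)) {
    x <- df[[nm]]
    y <- suppressWarnings(as.numeric(x))
    if (length(x) > 0L && all(is.na(y) == is.na(x)) && !all(is.na(x)))
      df[[nm]] <- y
  }
  df
}

#' Write a tab-separated table
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = NA_TOKEN,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_aa_string <- function(x) {
  grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), x)
}

# Split a string into single characters.
aa_chars <- function(x) strsplit(x, "")[[1]]
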