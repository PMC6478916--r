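# Readers and writers for the tabular and sequence formats used across the
# pipeline. Conventions: TSV, UTF-8, header row, '.' for missing; protein
# positions 1-based in files; peptide window offsets 0-based internally.

#' Read a missense mutation table
#'
#' Expects columns `patient_id`, `gene`, `protein_context`, `position`,
#' `ref`, `alt`. `position` is the 1-based index of the substituted residue
#' within `protein_context`; the context must carry the reference residue
#' there. Rows violating the invariants are rejected with row-numbered
#' errors; unknown extra columns are ignored.
#'
#' @param path TSV path.
#' @return Data frame of validated mutation records.
#' @export
read_mutations <- function(path) {
  df <- read_tsv(path, required = c("patient_id", "gene", "protein_context",
                                    "position", "ref", "alt"))
  if (nrow(df) == 0L) return(df)
  df$position <- as.integer(df$position)
  validate_mutations(df, origin = path)
}

validate_mutations <- function(df, origin = "<mutations>") {
  for (i in seq_len(nrow(df))) {
    ctx <- df$protein_context[i]
    pos <- df$position[i]
    if (is.na(pos) || pos < 1L || pos > nchar(ctx))
      stopf("validation error in '%s' row %d: position %s outside context",
            origin, i, format(pos))
    if (substr(ctx, pos, pos) != df$ref[i])
      stopf("validation error in '%s' row %d: context has '%s' at position %d, not ref '%s'",
            origin, i, substr(ctx, pos, pos), pos, df$ref[i])
    if (df$ref[i] == df$alt[i])
      stopf("validation error in '%s' row %d: ref equals alt", origin, i)
    if (!all(c(df$ref[i], df$alt[i]) %in% AA_ALPHABET) || !is_aa_string(ctx))
      stopf("validation error in '%s' row %d: non-standard residue", origin, i)
  }
  df
}

#' Read a peptide-allele binding affinity table
#'
#' Expects columns `peptide`, `allele`, `ic50_nM`. Duplicate
#' (peptide, allele) keys keep the first value with a warning; non-positive
#' IC50s are errors. The result is an affinity lookup for
#' [affinity_query()].
#'
#' @param path TSV path.
#' @return An object of class `affinity_lookup`.
#' @export
read_affinities <- function(path) {
  df <- read_tsv(path, required = c("peptide", "allele", "ic50_nM"))
  df$ic50_nM <- as.numeric(df$ic50_nM)
  affinity_lookup(df)
}

#' Build an affinity lookup from a data frame
#'
#' @param df Data frame with columns `peptide`, `allele`, `ic50_nM`.
#' @return An object of class `affinity_lookup` supporting exact-key query.
#' @export
affinity_lookup <- function(df) {
  if (any(is.na(df$ic50_nM)) || any(df$ic50_nM <= 0))
    stopf("validation error: non-positive or missing IC50")
  if (any(nchar(df$peptide) != 9L))
    stopf("validation error: affinity peptides must be 9-mers")
  key <- paste(df$peptide, df$allele, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    warnf("%d duplicate affinity key(s); keeping first occurrence", sum(dup))
    df <- df[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  structure(list(keys = key, values = df$ic50_nM, n = nrow(df)),
            class = "affinity_lookup")
}

#' Query an affinity lookup
#'
#' @param lookup An `affinity_lookup`.
#' @param peptide,allele Key components (vectorised, recycled).
#' @return Numeric IC50 vector; `NA` where the key is absent (a missing
#'   affinity is signalled, never defaulted).
#' @export
affinity_query <- function(lookup, peptide, allele) {
  key <- paste(peptide, allele, sep = "|")
  lookup$values[match(key, lookup$keys)]
}

#' @export
print.affinity_lookup <- function(x, ...) {
  cat(sprintf("Affinity lookup with %d (peptide, allele) entries\n", x$n))
  invisible(x)
}

#' Read a clinical table
#'
#' Expects columns `patient_id`, `survival_days`, `event`, and optionally
#' `age`, `gender`, `mutation_load`.
#'
#' @param path TSV path.
#' @return Data frame of clinical records.
#' @export
read_clinical <- function(path) {
  df <- read_tsv(path, required = c("patient_id", "survival_days", "event"))
  df$survival_days <- as.numeric(df$survival_days)
  df$event <- as.integer(df$event)
  if (any(df$survival_days < 0, na.rm = TRUE))
    stopf("validation error: negative survival time")
  if (!all(df$event %in% c(0L, 1L)))
    stopf("validation error: event must be 0/1")
  df
}

#' Read HLA caller tables
#'
#' Long format: columns `caller`, `patient_id`, `locus`, `allele1`,
#' `allele2` with four-digit names such as `HLA-A*02:01`; `.` where a
#' caller made no call.
#'
#' @param path TSV path.
#' @return Data frame of caller calls.
#' @export
read_hla_calls <- function(path) {
  read_tsv(path, required = c("caller", "patient_id", "locus",
                              "allele1", "allele2"))
}

#' Read an epitope database
#'
#' FASTA input yields sequences only; TSV input (columns `sequence`, and
#' optionally `assay_type`, `qualitative`) carries immunogenicity labels in
#' the style of IEDB exports (`positive high` / `negative`).
#'
#' @param path FASTA (`.fa`, `.fasta`) or TSV path.
#' @return Data frame with columns `sequence`, `assay_type`, `qualitative`
#'   (label columns `NA` for FASTA input).
#' @export
read_epitopes <- function(path) {
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    seqs <- as.character(Biostrings::readAAStringSet(path))
    df <- data.frame(sequence = unname(seqs),
                     assay_type = NA_character_,
                     qualitative = NA_character_,
                     stringsAsFactors = FALSE)
  } else {
    df <- read_tsv(path, required = "sequence")
    if (is.null(df$assay_type)) df$assay_type <- NA_character_
    if (is.null(df$qualitative)) df$qualitative <- NA_character_
  }
  if (nrow(df) == 0L) stopf("validation error: empty epitope database")
  if (any(nchar(df$sequence) < 8L))
    stopf("validation error: epitope shorter than 8 residues")
  df
}

#' Read gene-set signatures in GMT-like format
#'
#' Each line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT path.
#' @return Named list of unique gene symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("format error: GMT line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene-set signatures in GMT-like format
#'
#' @param sets Named list of gene vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression or methylation matrix
#'
#' TSV with features in rows (first column = feature id) and samples in
#' columns.
#'
#' @param path TSV path.
#' @return Numeric matrix with feature rownames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = NA_TOKEN, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_col Name of the first (feature id) column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}
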