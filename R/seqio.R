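# Sequence I/O.
#
# Sequence collections are named character vectors: names are record ids
# (first whitespace-delimited token of the header), values are uppercase
# IUPAC residue strings, optionally gapped with '-'. Full headers are kept
# in the "descriptions" attribute. Parsing goes through Biostrings; this
# layer adds normalization (case, U->T, '.'->'-') and strict validation.

normalize_residues <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  gsub(".", "-", x, fixed = TRUE)
}

validate_residues <- function(seqs, allow_gap = TRUE) {
  pattern <- if (allow_gap) "[^ACGTRYSWKMBDHVN-]" else "[^ACGTRYSWKMBDHVN]"
  for (i in seq_along(seqs)) {
    hit <- regexpr(pattern, seqs[[i]])
    if (hit > 0L)
      stop(sprintf("record '%s': invalid character '%s' at position %d",
                   names(seqs)[i], substr(seqs[[i]], hit, hit), hit),
           call. = FALSE)
  }
  invisible(seqs)
}

as_seq_set <- function(seqs, descriptions = NULL) {
  seqs <- normalize_residues(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("every sequence record needs a non-empty id")
  if (anyDuplicated(names(seqs)))
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")))
  validate_residues(seqs)
  if (!is.null(descriptions)) attr(seqs, "descriptions") <- descriptions
  seqs
}

#' Read a FASTA file into a sequence set
#'
#' Residues are upper-cased, RNA `U` is mapped to `T`, and alignment dots
#' are normalized to `-`. Any other non-IUPAC character is a hard error
#' reported with its position. Record ids (first token of the header) must
#' be unique; the full header line is retained in the `"descriptions"`
#' attribute. Record order is preserved.
#'
#' @param path Path to a FASTA (or FASTQ, see `format`) file.
#' @param format `"fasta"` (default) or `"fastq"`; FASTQ qualities are
#'   parsed and discarded.
#' @return Named character vector of residue strings (a *sequence set*).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acg", "t"), f)
#' read_fasta(f)  # c(a = "ACGT")
#' @export
read_fasta <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  ss <- Biostrings::readBStringSet(path, format = format)
  if (length(ss) == 0L) {
    warning(sprintf("no sequence records in %s", path))
    return(as_seq_set(stats::setNames(character(0), character(0))))
  }
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  as_seq_set(stats::setNames(as.character(ss), ids), descriptions = headers)
}

#' Write a sequence set to FASTA
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line-wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  seqs <- as_seq_set(seqs, attr(seqs, "descriptions"))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

#' Read primers from a two-column TSV
#'
#' Expected columns: `name` and `sequence` (IUPAC codes allowed). Extra
#' columns are carried through untouched. Lines starting with `#` are
#' comments; a header row is auto-detected.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with at least `name` and `sequence` columns;
#'   sequences normalized to uppercase and validated.
#' @export
read_primer_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("name", "sequence") %in% names(df)))
    stop("primer TSV needs 'name' and 'sequence' columns")
  df$sequence <- normalize_residues(df$sequence)
  validate_residues(stats::setNames(df$sequence, df$name), allow_gap = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicate primer names in primer TSV")
  df
}

#' Write primers as a two-column TSV
#'
#' @param primers data.frame with `name` and `sequence` columns (extra
#'   columns are written too).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_tsv <- function(primers, path) {
  utils::write.table(primers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Path to a packaged example data file
#'
#' Convenience wrapper around `system.file()` for the fixtures shipped under
#' `extdata/`: the published LAB primer panel (`lab_primers.tsv`), the
#' per-sample read-count table (`lab_read_counts.tsv`) and the relative
#' abundance matrix (`lab_species_abundance.tsv`).
#'
#' @param file File name under `extdata/`; if missing, lists available files.
#' @return Absolute path (or a vector of file names).
#' @export
degeprimer_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "degeprimer")))
  path <- system.file("extdata", file, package = "degeprimer")
  if (path == "") stop(sprintf("no packaged example file '%s'", file))
  path
}
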