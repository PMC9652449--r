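# Standard-format I/O: FASTQ via Biostrings, headered TSV tables with CRLF
# tolerance, and round-trip guarantees for the package's internal tables.

#' Read a FASTQ file
#'
#' @param path FASTQ file (Sanger Phred+33).
#' @return List with `id` and `sequence` character vectors.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                error = function(e)
                  stop("malformed FASTQ '", path, "': ", conditionMessage(e),
                       call. = FALSE))
  if (!length(x)) stop("empty FASTQ input: ", path, call. = FALSE)
  # keep only the record identifier (up to first whitespace)
  ids <- sub("\\s.*$", "", names(x))
  list(id = ids, sequence = as.character(x, use.names = FALSE))
}

#' Write reads to FASTQ
#'
#' Writes Sanger Phred+33 records with constant quality `I`.
#'
#' @param reads A result from [simulate_edited_reads()], or a character
#'   vector of sequences.
#' @param path Output file.
#' @param id Read identifiers (defaults to the simulation ids or
#'   `read_<n>`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, id = NULL) {
  if (is.list(reads) && !is.null(reads$sequence)) {
    if (is.null(id)) id <- reads$id
    reads <- reads$sequence
  }
  if (is.null(id)) id <- sprintf("read_%06d", seq_along(reads))
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a headered TSV with required columns
#'
#' Tolerates CRLF line endings; reports missing columns by name.
#'
#' @param path TSV file.
#' @param required Character vector of required column names.
#' @return Data frame.
#' @export
read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- sub("\r$", "", readLines(path, warn = FALSE))
  if (!length(txt) || !nzchar(txt[1]))
    stop("empty table: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(text = paste(txt, collapse = "\n"),
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("TSV '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Write a table as TSV
#'
#' Headered, tab-separated, LF line endings, no quoting; the package's table
#' writers all round-trip through [read_tsv_checked()].
#'
#' @param df Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
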