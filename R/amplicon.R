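# Reference amplicon descriptions: sequence + protospacer annotation with the
# blunt cut site derived 3 bp 5' of the PAM (between protospacer positions 17
# and 18), never user-set.

#' Define a reference amplicon
#'
#' Bundles an amplicon sequence with its protospacer annotation and derives
#' the SpCas9 blunt cut-site coordinate. Protospacer positions are numbered
#' 1-20 in 5'->3' direction on the non-targeted strand (the strand whose
#' sequence equals the spacer); the cut site is the inter-base bond between
#' protospacer positions 17 and 18, i.e. 3 bp 5' of the PAM.
#'
#' @param name Amplicon identifier.
#' @param sequence Uppercase DNA string (ACGTN only).
#' @param protospacer_start 0-based reference index of protospacer position 1.
#' @param strand `"+"` if the protospacer reads 5'->3' along the amplicon
#'   sequence as given, `"-"` if along its reverse complement.
#' @param pam Expected 3-mer PAM (N is a wildcard); checked against the
#'   sequence immediately 3' of the protospacer.
#' @return An object of class `amplicon_ref` with fields `name`, `sequence`,
#'   `protospacer_start`, `strand`, `pam`, `protospacer` (20-mer, protospacer
#'   orientation) and the derived 0-based inter-base `cut_site`.
#' @examples
#' ref <- amplicon_reference("demo",
#'   sequence = paste0("AACCG", strrep("ACGT", 5), "TGGAACCTTGGACGTACGATCG"),
#'   protospacer_start = 5, strand = "+", pam = "TGG")
#' ref$cut_site  # protospacer_start + 17
#' @export
amplicon_reference <- function(name, sequence, protospacer_start,
                               strand = c("+", "-"), pam = "NGG") {
  strand <- match.arg(strand)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGTN]+$", sequence))
    stop("amplicon sequence must contain only A, C, G, T, N", call. = FALSE)
  protospacer_start <- as.integer(protospacer_start)
  m <- nchar(sequence)
  pam <- toupper(pam)
  if (nchar(pam) != 3L)
    stop("pam must be a 3-mer", call. = FALSE)

  if (strand == "+") {
    if (protospacer_start < 0L || protospacer_start + 23L > m)
      stop("protospacer (plus PAM) does not fit inside the amplicon",
           call. = FALSE)
    protospacer <- substr(sequence, protospacer_start + 1L,
                          protospacer_start + 20L)
    pam_obs <- substr(sequence, protospacer_start + 21L,
                      protospacer_start + 23L)
    cut_site <- protospacer_start + 17L
  } else {
    if (protospacer_start - 19L < 0L || protospacer_start - 22L < 0L ||
        protospacer_start + 1L > m)
      stop("protospacer (plus PAM) does not fit inside the amplicon",
           call. = FALSE)
    protospacer <- revcomp(substr(sequence, protospacer_start - 19L + 1L,
                                  protospacer_start + 1L))
    pam_obs <- revcomp(substr(sequence, protospacer_start - 22L + 1L,
                              protospacer_start - 20L + 1L))
    cut_site <- protospacer_start - 16L
  }
  if (!pam_compatible(pam_obs, pam))
    stop(sprintf("PAM mismatch: annotation says %s, sequence has %s",
                 pam, pam_obs), call. = FALSE)
  if (cut_site <= 0L || cut_site >= m)
    stop("derived cut site falls outside the amplicon", call. = FALSE)

  structure(
    list(name = name, sequence = sequence,
         protospacer_start = protospacer_start, strand = strand,
         pam = pam_obs, protospacer = protospacer, cut_site = cut_site),
    class = "amplicon_ref")
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat(sprintf("<amplicon_ref> %s: %d bp, protospacer %s (%s strand), PAM %s, cut site %d\n",
              x$name, nchar(x$sequence), x$protospacer, x$strand, x$pam,
              x$cut_site))
  invisible(x)
}

# N in the expected PAM is a wildcard; N in the sequence matches nothing but N.
pam_compatible <- function(observed, expected) {
  eo <- strsplit(expected, "")[[1]]
  ob <- strsplit(observed, "")[[1]]
  all(eo == "N" | eo == ob)
}

#' Map protospacer positions to 0-based reference indices
#'
#' @param ref An `amplicon_ref`.
#' @param positions Protospacer positions (1-20, numbered 5'->3' on the
#'   non-targeted strand).
#' @return Integer vector of 0-based reference indices.
#' @export
protospacer_ref_index <- function(ref, positions = 1:20) {
  stopifnot(inherits(ref, "amplicon_ref"))
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > 20L))
    stop("protospacer positions must lie in 1..20", call. = FALSE)
  if (ref$strand == "+") ref$protospacer_start + (positions - 1L)
  else ref$protospacer_start - (positions - 1L)
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (ACGTN).
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Read amplicon references from FASTA plus an annotation table
#'
#' The annotation TSV must have columns `name`, `protospacer_start` (0-based),
#' `strand` and `pam`; every annotated name must be present in the FASTA.
#'
#' @param fasta Path to a FASTA file of amplicon sequences.
#' @param annotation Path to the annotation TSV.
#' @return Named list of `amplicon_ref` objects.
#' @export
read_amplicons <- function(fasta, annotation) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ann <- read_tsv_checked(annotation,
                          c("name", "protospacer_start", "strand", "pam"))
  missing <- setdiff(ann$name, names(seqs))
  if (length(missing))
    stop("annotated amplicons missing from FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(ann)), function(i) {
    amplicon_reference(ann$name[i],
                       as.character(seqs[[ann$name[i]]]),
                       ann$protospacer_start[i],
                       ann$strand[i], ann$pam[i])
  })
  names(out) <- ann$name
  out
}
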