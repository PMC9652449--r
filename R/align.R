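# Read-to-amplicon alignment. Reads are short PCR-amplicon sequences, so a
# fitting (semiglobal) alignment against the amplicon is used: the read is
# consumed end to end, unaligned reference overhang is free. Defaults
# penalise scattered mismatches relative to one clean indel near the cut,
# which matches the one-indel-event read model of amplicon editing data.

#' Default alignment scoring scheme
#'
#' Match +1, mismatch -4, gap open -6, gap extend -1; a gap of length L costs
#' `gap_open + L * gap_extend`. Read end-gaps against reference overhang are
#' free.
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores/penalties.
#' @return A named list used by the alignment functions.
#' @export
alignment_scoring <- function(match = 1L, mismatch = -4L, gap_open = -6L,
                              gap_extend = -1L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

op_names <- c("match", "mismatch", "insertion", "deletion")

ops_to_segments <- function(ops, ref_start) {
  if (!length(ops)) {
    return(data.frame(op = character(), length = integer(),
                      ref_start = integer(), read_start = integer(),
                      stringsAsFactors = FALSE))
  }
  r <- rle(ops)
  k <- length(r$values)
  ref_pos <- integer(k); read_pos <- integer(k)
  ri <- 0L; rj <- ref_start
  for (i in seq_len(k)) {
    ref_pos[i] <- rj; read_pos[i] <- ri
    len <- r$lengths[i]
    v <- r$values[i]
    if (v == 1L || v == 2L) { ri <- ri + len; rj <- rj + len }
    else if (v == 3L) ri <- ri + len
    else rj <- rj + len
  }
  data.frame(op = op_names[r$values], length = as.integer(r$lengths),
             ref_start = ref_pos, read_start = read_pos,
             stringsAsFactors = FALSE)
}

segments_to_ops <- function(segments) {
  code <- match(segments$op, op_names)
  rep(code, segments$length)
}

#' Align a read semiglobally to a reference amplicon
#'
#' Both orientations of the read are aligned and the higher-scoring one kept
#' (forward on ties). Equal-scoring indel placements are canonicalised to the
#' lowest reference coordinate (left-aligned).
#'
#' @param read DNA string (ACGTN), length >= 25.
#' @param ref An [amplicon_reference()] object, or a plain DNA string.
#' @param id Read identifier carried through to the result.
#' @param scoring Scoring scheme from [alignment_scoring()].
#' @return An object of class `aligned_read`: list with `id`, `score`,
#'   `orientation` (`"+"`/`"-"`), `read` (sequence in aligned orientation),
#'   and `segments`, a data frame of `op` (match/mismatch/insertion/deletion),
#'   `length`, `ref_start`, `read_start` (0-based; insertion `ref_start` is
#'   the inter-base insertion point). Rejected reads (non-ACGTN characters)
#'   return class `aligned_read` with `ok = FALSE` and a `reason` code.
#' @examples
#' a <- align_semiglobal("ACGACGT", "ACGTACGT")
#' a$segments
#' @export
align_semiglobal <- function(read, ref, id = "read",
                             scoring = alignment_scoring()) {
  refseq <- if (inherits(ref, "amplicon_ref")) ref$sequence else toupper(ref)
  read <- toupper(read)
  if (!grepl("^[ACGTN]+$", read)) {
    return(structure(list(id = id, ok = FALSE, reason = "non_acgtn"),
                     class = "aligned_read"))
  }
  fwd <- .cq_align_one(read, refseq, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  rcread <- revcomp(read)
  rev <- .cq_align_one(rcread, refseq, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  if (rev$score > fwd$score) {
    a <- rev; orientation <- "-"; seq <- rcread
  } else {
    a <- fwd; orientation <- "+"; seq <- read
  }
  structure(list(id = id, ok = TRUE, score = a$score,
                 orientation = orientation, read = seq,
                 ref_start = a$ref_start,
                 segments = ops_to_segments(a$ops, a$ref_start)),
            class = "aligned_read")
}

#' @export
print.aligned_read <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat(sprintf("<aligned_read> %s: rejected (%s)\n", x$id, x$reason))
    return(invisible(x))
  }
  cat(sprintf("<aligned_read> %s: score %d, orientation %s, CIGAR %s\n",
              x$id, x$score, x$orientation, alignment_cigar(x)))
  invisible(x)
}

#' CIGAR-style operation string of an alignment
#'
#' Uses `=` (match), `X` (mismatch), `I` (insertion), `D` (deletion).
#'
#' @param a An `aligned_read`.
#' @return A single string.
#' @export
alignment_cigar <- function(a) {
  stopifnot(inherits(a, "aligned_read"), isTRUE(a$ok))
  code <- c(match = "=", mismatch = "X", insertion = "I", deletion = "D")
  paste0(a$segments$length, code[a$segments$op], collapse = "")
}

#' Left-align all indels in an alignment
#'
#' Shifts every insertion/deletion run to its minimal reference coordinate
#' among sequence-equivalent placements. Idempotent; the reconstructed read
#' is unchanged.
#'
#' @param a An `aligned_read`.
#' @param ref Reference amplicon (object or string).
#' @return The `aligned_read` with canonical indel placement.
#' @export
left_align_indels <- function(a, ref) {
  stopifnot(inherits(a, "aligned_read"), isTRUE(a$ok))
  refseq <- if (inherits(ref, "amplicon_ref")) ref$sequence else toupper(ref)
  ops <- .cq_left_align(segments_to_ops(a$segments), a$ref_start, a$read,
                        refseq)
  a$segments <- ops_to_segments(ops, a$ref_start)
  a
}

#' Reference-prefix identity filter
#'
#' Implements the amplicon read filter: a read passes if at least
#' `ceiling(min_frac * prefix_len)` of the first `prefix_len` reference
#' positions are covered by match columns. Mismatched and deletion-covered
#' positions count as unmatched. With the defaults this is the
#' at-least-75%-of-the-first-20-bp rule (threshold 15/20).
#'
#' @param a An `aligned_read`.
#' @param ref Reference amplicon (unused beyond interface symmetry).
#' @param prefix_len Number of leading reference positions inspected.
#' @param min_frac Minimum fraction of matched positions.
#' @return `TRUE`/`FALSE`.
#' @export
prefix_identity <- function(a, ref = NULL, prefix_len = 20L,
                            min_frac = 0.75) {
  stopifnot(inherits(a, "aligned_read"))
  if (!isTRUE(a$ok)) return(FALSE)
  seg <- a$segments
  m <- seg[seg$op == "match", , drop = FALSE]
  matched <- 0L
  if (nrow(m)) {
    lo <- pmax(m$ref_start, 0L)
    hi <- pmin(m$ref_start + m$length, prefix_len)
    matched <- sum(pmax(hi - lo, 0L))
  }
  matched >= ceiling(min_frac * prefix_len)
}

#' Reconstruct the read sequence from an alignment
#'
#' Applies the alignment segments to the reference; the result must equal the
#' aligned read sequence exactly (a package invariant used in testing).
#'
#' @param a An `aligned_read`.
#' @param ref Reference amplicon (object or string).
#' @return The reconstructed read string.
#' @export
reconstruct_read <- function(a, ref) {
  stopifnot(inherits(a, "aligned_read"), isTRUE(a$ok))
  refseq <- if (inherits(ref, "amplicon_ref")) ref$sequence else toupper(ref)
  out <- character(nrow(a$segments))
  for (i in seq_len(nrow(a$segments))) {
    s <- a$segments[i, ]
    out[i] <- switch(s$op,
      match = ,
      mismatch = substr(a$read, s$read_start + 1L, s$read_start + s$length),
      insertion = substr(a$read, s$read_start + 1L, s$read_start + s$length),
      deletion = "")
  }
  paste(out, collapse = "")
}

#' Exhaustive reference scorer for semiglobal alignment
#'
#' Independent formulation of the optimal semiglobal alignment score used to
#' validate the production aligner: instead of Gotoh state matrices it
#' enumerates, for every cell, whole gap runs (and adjacent insertion+deletion
#' run pairs) by explicit maximisation. Intended for small inputs only.
#'
#' @param read,ref DNA strings.
#' @param scoring Scoring scheme from [alignment_scoring()].
#' @return The optimal alignment score (integer).
#' @export
align_score_exhaustive <- function(read, ref, scoring = alignment_scoring()) {
  read <- strsplit(toupper(read), "")[[1]]
  ref <- strsplit(toupper(ref), "")[[1]]
  n <- length(read); m <- length(ref)
  gap <- function(k) scoring$gap_open + k * scoring$gap_extend
  NEG <- -1e9
  # B[i+1, j+1]: best score of an alignment of read[1..i] whose last column
  # aligns read[i] with ref[j] (B[1, j+1] = 0: free reference prefix, nothing
  # consumed yet).
  B <- matrix(NEG, n + 1L, m + 1L)
  B[1L, ] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (read[i] == ref[j] && read[i] != "N") scoring$match
           else scoring$mismatch
      best <- B[i, j]                                   # aligned predecessor
      if (i >= 2L) {                                    # insertion run
        k <- seq_len(i - 1L)
        best <- max(best, max(B[i - k, j] + gap(k)))
      }
      if (j >= 2L) {                                    # deletion run
        k <- seq_len(j - 1L)
        best <- max(best, max(B[i, j - k] + gap(k)))
      }
      if (i >= 2L && j >= 2L) {                         # adjacent ins+del runs
        for (ki in seq_len(i - 1L)) {
          kj <- seq_len(j - 1L)
          best <- max(best, max(B[i - ki, j - kj] + gap(ki) + gap(kj)))
        }
      }
      B[i + 1L, j + 1L] <- best + s
    }
  }
  # free reference suffix; alignment may end aligned or with an insertion run
  best <- max(B[n + 1L, ])
  if (n >= 1L) {
    for (k in seq_len(n)) {
      cand <- max(B[n + 1L - k, ]) + gap(k)
      if (cand > best) best <- cand
    }
  }
  as.integer(best)
}

# Batch alignment of many reads to one amplicon; returns the flat structure
# produced by the C++ core plus derived pass/fail of the prefix filter.
# Internal fast path used by quantify_sample() and the pipeline.
align_batch <- function(reads, ref, scoring = alignment_scoring(),
                        prefix_len = 20L, min_frac = 0.75) {
  stopifnot(inherits(ref, "amplicon_ref"))
  proto_idx <- protospacer_ref_index(ref, 1:20)
  b <- .cq_align_batch(as.character(reads), ref$sequence, scoring$match,
                       scoring$mismatch, scoring$gap_open, scoring$gap_extend,
                       as.integer(prefix_len), as.integer(proto_idx))
  b$pass_prefix <- !is.na(b$prefix_matches) &
    b$prefix_matches >= ceiling(min_frac * prefix_len)
  # protospacer bases are reported in protospacer orientation (5'->3' on the
  # non-targeted strand); complement for minus-strand amplicons
  if (ref$strand == "-" && length(b$proto)) {
    b$proto <- ifelse(is.na(b$proto), NA,
                      chartr("ACGTN", "TGCAN", b$proto))
  }
  b$n <- length(reads)
  b$ref <- ref
  b
}

#' Align reads and export per-read alignment records
#'
#' Convenience wrapper for file-level use: aligns every read in a FASTQ file
#' to one amplicon and returns a per-read table with score, orientation and a
#' CIGAR-style op string.
#'
#' @param fastq Path to a FASTQ file.
#' @param ref An `amplicon_ref`.
#' @param scoring Scoring scheme.
#' @param prefix_len,min_frac Prefix-identity filter parameters.
#' @return Data frame with columns `id`, `valid`, `score`, `orientation`,
#'   `ref_start`, `prefix_matches`, `pass_prefix`, `cigar`.
#' @export
align_reads <- function(fastq, ref, scoring = alignment_scoring(),
                        prefix_len = 20L, min_frac = 0.75) {
  rs <- read_fastq(fastq)
  b <- align_batch(rs$sequence, ref, scoring, prefix_len, min_frac)
  cigar <- rep(NA_character_, b$n)
  ok <- which(b$valid)
  for (i in ok) {
    a <- align_semiglobal(rs$sequence[i], ref, id = rs$id[i], scoring)
    cigar[i] <- alignment_cigar(a)
  }
  data.frame(id = rs$id, valid = b$valid, score = b$score,
             orientation = ifelse(b$is_rev, "-", "+"),
             ref_start = b$ref_start, prefix_matches = b$prefix_matches,
             pass_prefix = b$pass_prefix, cigar = cigar,
             stringsAsFactors = FALSE)
}
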