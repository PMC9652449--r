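# Per-read outcome classification and per-sample quantification. The calling
# rules follow the standard amplicon-NGS conventions: reads must match at
# least 75% of the first 20 reference bases; indels are called when their
# left-aligned start lies within +/-2 bp of the cut site; base edits are
# "intended modification present, no indels"; prime edits are "only the
# intended insertion/deletion"; dsODN tag integration is detected by exact
# occurrence of the tag's center 15-mer in either orientation.

#' Specify the intended edit(s) of a sample
#'
#' @param amplicon The [amplicon_reference()] the sample was sequenced
#'   against.
#' @param substitutions Optional data frame with columns `position`
#'   (protospacer 1-20), `from`, `to` (bases on the non-targeted strand).
#' @param intended_indel Optional prime edit: list with `type` (`"insertion"`
#'   or `"deletion"`), `position` (0-based reference coordinate, canonical
#'   left-aligned form), `sequence` (insertions) or `length` (deletions).
#' @param window Inclusive protospacer position range of the base-editing
#'   window; default positions 4-8.
#' @return A validated `edit_spec` object.
#' @export
edit_spec <- function(amplicon, substitutions = NULL, intended_indel = NULL,
                      window = c(4L, 8L)) {
  stopifnot(inherits(amplicon, "amplicon_ref"))
  window <- as.integer(window)
  stopifnot(length(window) == 2L, window[1] <= window[2],
            window[1] >= 1L, window[2] <= 20L)
  if (!is.null(substitutions)) {
    substitutions <- as.data.frame(substitutions)
    stopifnot(all(c("position", "from", "to") %in% names(substitutions)))
    if (any(substitutions$position < 1 | substitutions$position > 20))
      stop("substitution positions must lie in 1..20", call. = FALSE)
    refb <- proto_base_at(amplicon, substitutions$position)
    bad <- toupper(substitutions$from) != refb
    if (any(bad))
      stop("substitution from-base does not match the reference at position ",
           paste(substitutions$position[bad], collapse = ","), call. = FALSE)
  }
  if (!is.null(intended_indel)) {
    pe <- intended_indel
    pe$frequency <- 0   # reuse the simulator validator for geometry checks
    intended_indel <- validate_prime_edit(pe, amplicon)
    intended_indel$frequency <- NULL
  }
  structure(list(amplicon = amplicon, substitutions = substitutions,
                 intended_indel = intended_indel, window = window),
            class = "edit_spec")
}

# window test shared by the scalar and vectorised paths: an indel is at the
# cut if its left-aligned start (first deleted base, or inter-base insertion
# point) lies within window_bp of the cut-site coordinate
indel_in_window <- function(ref_start, cut_site, window_bp = 2L) {
  ref_start >= cut_site - window_bp & ref_start <= cut_site + window_bp
}

#' Call a cut-site indel on one aligned read
#'
#' Returns an indel call if at least one insertion or deletion segment has a
#' (left-aligned) reference start within `window_bp` of the cut site.
#' Substitution-only reads, and reads whose indels all start outside the
#' window, return `NULL`. By default distal mismatches do not veto the call;
#' `strict_read = TRUE` additionally requires the whole read to be
#' mismatch-free.
#'
#' @param a An `aligned_read` (already left-aligned, as produced by
#'   [align_semiglobal()]).
#' @param ref The `amplicon_ref`.
#' @param window_bp Half-width of the calling window around the cut (bp).
#' @param strict_read Require a mismatch-free read.
#' @return `NULL`, or a list with `type`, `length`, `ref_start`.
#' @export
call_indel <- function(a, ref, window_bp = 2L, strict_read = FALSE) {
  stopifnot(inherits(a, "aligned_read"), inherits(ref, "amplicon_ref"))
  if (!isTRUE(a$ok)) return(NULL)
  seg <- a$segments
  if (strict_read && any(seg$op == "mismatch")) return(NULL)
  ind <- seg[seg$op %in% c("insertion", "deletion") &
               indel_in_window(seg$ref_start, ref$cut_site, window_bp), ,
             drop = FALSE]
  if (!nrow(ind)) return(NULL)
  list(type = ind$op[1], length = ind$length[1], ref_start = ind$ref_start[1])
}

# read base observed at each protospacer position (protospacer orientation);
# "-" = deleted, "." = not covered by the alignment
proto_bases <- function(a, ref) {
  idx <- protospacer_ref_index(ref, 1:20)
  out <- rep(".", 20L)
  seg <- a$segments
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (s$op %in% c("match", "mismatch")) {
      hit <- which(idx >= s$ref_start & idx < s$ref_start + s$length)
      if (length(hit)) {
        off <- idx[hit] - s$ref_start
        out[hit] <- substring(a$read, s$read_start + off + 1L,
                              s$read_start + off + 1L)
      }
    } else if (s$op == "deletion") {
      hit <- which(idx >= s$ref_start & idx < s$ref_start + s$length)
      out[hit] <- "-"
    }
  }
  if (ref$strand == "-") out <- chartr("ACGTN", "TGCAN", out)
  out
}

#' Call a base edit on one aligned read
#'
#' Reports the read base at every protospacer position (1-20, 5'->3' on the
#' non-targeted strand) and whether the read carries the intended
#' modification: all specified substitutions present and no indel segment
#' anywhere in the alignment.
#'
#' @param a An `aligned_read`.
#' @param ref The `amplicon_ref`.
#' @param spec An [edit_spec()] with substitutions.
#' @return List with `positions` (character vector of 20 bases; `"-"` deleted,
#'   `"."` uncovered) and `intended` (logical).
#' @export
call_base_edit <- function(a, ref, spec) {
  stopifnot(inherits(a, "aligned_read"), inherits(spec, "edit_spec"))
  if (!isTRUE(a$ok)) return(list(positions = rep(NA_character_, 20L),
                                 intended = FALSE))
  bases <- proto_bases(a, ref)
  has_indel <- any(a$segments$op %in% c("insertion", "deletion"))
  intended <- FALSE
  if (!is.null(spec$substitutions) && nrow(spec$substitutions) && !has_indel) {
    intended <- all(bases[spec$substitutions$position] ==
                      toupper(spec$substitutions$to))
  }
  list(positions = bases, intended = intended)
}

# does one indel segment equal the intended edit exactly?
segment_equals_intended <- function(op, ref_start, len, seq, intended) {
  if (intended$type == "insertion") {
    op == "insertion" & ref_start == intended$position &
      len == intended$length & seq == intended$sequence
  } else {
    op == "deletion" & ref_start == intended$position &
      len == intended$length
  }
}

#' Call a prime edit on one aligned read
#'
#' `"intended_pe"` if the alignment's indel content is exactly the intended
#' edit (same type, left-aligned position and sequence) and nothing else;
#' `"background_indel"` if at least one indel differs from the intended edit
#' (including reads carrying the intended edit plus extra indels);
#' `"none"` for indel-free reads.
#'
#' @param a An `aligned_read`.
#' @param ref The `amplicon_ref`.
#' @param spec An [edit_spec()] with an `intended_indel`.
#' @return One of `"intended_pe"`, `"background_indel"`, `"none"`.
#' @export
call_prime_edit <- function(a, ref, spec) {
  stopifnot(inherits(a, "aligned_read"), inherits(spec, "edit_spec"))
  if (is.null(spec$intended_indel))
    stop("edit_spec has no intended indel; call_prime_edit requires one",
         call. = FALSE)
  if (!isTRUE(a$ok)) return("none")
  seg <- a$segments[a$segments$op %in% c("insertion", "deletion"), ,
                    drop = FALSE]
  if (!nrow(seg)) return("none")
  seqs <- vapply(seq_len(nrow(seg)), function(i) {
    if (seg$op[i] == "insertion")
      substr(a$read, seg$read_start[i] + 1L, seg$read_start[i] + seg$length[i])
    else ""
  }, character(1))
  eq <- segment_equals_intended(seg$op, seg$ref_start, seg$length, seqs,
                                spec$intended_indel)
  if (all(eq) && nrow(seg) == 1L) "intended_pe" else "background_indel"
}

#' Detect the GUIDE-seq dsODN tag in a read
#'
#' A read is tagged iff it contains the dsODN center 15-mer
#' `GTTGTCATATGTTAA` or its reverse complement `TTAACATATGACAAC` as an exact
#' substring (case-insensitive). Single-substitution decoys are not detected.
#'
#' @param read Character vector of read sequences (raw or aligned).
#' @return Logical vector.
#' @export
detect_dsodn_tag <- function(read) {
  x <- toupper(read)
  grepl(DSODN_15MER_F, x, fixed = TRUE) | grepl(DSODN_15MER_R, x, fixed = TRUE)
}

#' Quantify editing outcomes for one sample
#'
#' Aligns all reads to the amplicon, applies the reference-prefix identity
#' filter, classifies every read under the requested mode and returns
#' per-class counts and frequencies. Class precedence within a mode is
#' tag > intended prime edit > cut-site indel > intended substitution >
#' unedited; each mode only assigns the classes it quantifies.
#'
#' Modes: `"nuclease"` (indel vs unedited), `"base_editor"` (adds
#' `intended_sub`), `"prime_editor"` (`intended_pe` / `background_indel`),
#' `"tag"` (dsODN tag, then indel), `"all"` (every class; used against
#' simulator truth tables).
#'
#' @param reads Character vector of read sequences, a data frame with
#'   `id`/`sequence` columns, a simulation result from
#'   [simulate_edited_reads()], or a FASTQ path.
#' @param ref The `amplicon_ref`.
#' @param spec An [edit_spec()]; required for base/prime editor modes.
#' @param mode Quantification mode (see Details).
#' @param sample_id Sample label for the outcome table.
#' @param scoring Alignment scoring scheme.
#' @param prefix_len,min_frac Prefix-identity filter parameters (defaults:
#'   75% of the first 20 bp).
#' @param window_bp Indel window half-width around the cut site (default 2).
#' @param strict_indel_read Require indel-bearing reads to be mismatch-free.
#' @param count_discarded Use all reads as the frequency denominator instead
#'   of reads passing the prefix filter.
#' @return A list of class `sample_quant`: `outcome` (one-row data frame of
#'   counts and frequencies), `calls` (per-read class table), `alleles`
#'   (aggregated sequence/class/count table).
#' @export
quantify_sample <- function(reads, ref, spec = NULL,
                            mode = c("nuclease", "base_editor",
                                     "prime_editor", "tag", "all"),
                            sample_id = "sample",
                            scoring = alignment_scoring(),
                            prefix_len = 20L, min_frac = 0.75,
                            window_bp = 2L, strict_indel_read = FALSE,
                            count_discarded = FALSE) {
  mode <- match.arg(mode)
  rd <- normalize_reads(reads)
  if (!length(rd$sequence)) stop("no reads supplied", call. = FALSE)
  if (mode %in% c("base_editor") &&
      (is.null(spec) || is.null(spec$substitutions)))
    stop("base_editor mode requires an edit_spec with substitutions",
         call. = FALSE)
  if (mode == "prime_editor" && (is.null(spec) ||
                                 is.null(spec$intended_indel)))
    stop("prime_editor mode requires an edit_spec with an intended indel",
         call. = FALSE)

  n <- length(rd$sequence)
  b <- align_batch(rd$sequence, ref, scoring, prefix_len, min_frac)
  cut <- ref$cut_site

  discarded <- !b$valid | !b$pass_prefix
  reason <- ifelse(!b$valid, "non_acgtn",
                   ifelse(!b$pass_prefix, "prefix_filter", ""))

  ## vectorised per-read flags
  tag_hit <- detect_dsodn_tag(rd$sequence)

  nseg <- length(b$seg_read)
  seg_count <- tabulate(b$seg_read, nbins = n)
  indel_win <- rep(FALSE, n)
  if (nseg) {
    inw <- indel_in_window(b$seg_ref_start, cut, window_bp)
    indel_win[unique(b$seg_read[inw])] <- TRUE
    if (strict_indel_read) indel_win <- indel_win & b$n_mismatch == 0L
  }

  pe_hit <- rep(FALSE, n); bg_hit <- rep(FALSE, n)
  if (!is.null(spec) && !is.null(spec$intended_indel) && nseg) {
    opname <- c("match", "mismatch", "insertion", "deletion")[b$seg_op]
    eq <- segment_equals_intended(opname, b$seg_ref_start, b$seg_len,
                                  b$seg_seq, spec$intended_indel)
    one_seg <- seg_count == 1L
    pe_hit[b$seg_read[eq & one_seg[b$seg_read]]] <- TRUE
    bg_hit <- seg_count > 0L & !pe_hit
  }

  sub_hit <- rep(FALSE, n)
  if (!is.null(spec) && !is.null(spec$substitutions) &&
      nrow(spec$substitutions)) {
    ok <- rep(TRUE, n)
    for (j in seq_len(nrow(spec$substitutions))) {
      p <- spec$substitutions$position[j]
      ok <- ok & !is.na(b$proto) &
        substr(b$proto, p, p) == toupper(spec$substitutions$to[j])
    }
    sub_hit <- ok & !b$has_indel
  }

  ## mode-scoped precedence
  cls <- rep("unedited", n)
  if (mode == "nuclease") {
    cls[indel_win] <- "indel"
  } else if (mode == "base_editor") {
    cls[sub_hit] <- "intended_sub"
    cls[indel_win] <- "indel"
  } else if (mode == "prime_editor") {
    cls[bg_hit] <- "background_indel"
    cls[pe_hit] <- "intended_pe"
  } else if (mode == "tag") {
    cls[indel_win] <- "indel"
    cls[tag_hit] <- "tag"
  } else { # all
    cls[sub_hit] <- "intended_sub"
    cls[indel_win] <- "indel"
    if (!is.null(spec) && !is.null(spec$intended_indel)) cls[pe_hit] <-
        "intended_pe"
    cls[tag_hit] <- "tag"
  }
  cls[discarded] <- "discarded"

  counts <- c(discarded = sum(cls == "discarded"),
              unedited = sum(cls == "unedited"),
              indel = sum(cls == "indel"),
              intended_sub = sum(cls == "intended_sub"),
              intended_pe = sum(cls == "intended_pe"),
              background_indel = sum(cls == "background_indel"),
              tag = sum(cls == "tag"))
  denom <- if (count_discarded) n else n - counts[["discarded"]]
  warn <- denom == 0L
  if (warn) {
    warning("no reads passed the prefix-identity filter; frequencies are ",
            "reported over total reads", call. = FALSE)
    denom <- n
  }
  outcome <- data.frame(
    sample_id = sample_id, mode = mode, total_reads = n,
    n_discarded = counts[["discarded"]], n_unedited = counts[["unedited"]],
    n_indel = counts[["indel"]], n_intended_sub = counts[["intended_sub"]],
    n_intended_pe = counts[["intended_pe"]],
    n_background_indel = counts[["background_indel"]], n_tag = counts[["tag"]],
    denominator = denom,
    indel_freq = counts[["indel"]] / denom,
    sub_freq = counts[["intended_sub"]] / denom,
    pe_freq = counts[["intended_pe"]] / denom,
    background_freq = counts[["background_indel"]] / denom,
    tag_freq = counts[["tag"]] / denom,
    no_passing_reads = warn, stringsAsFactors = FALSE)

  calls <- data.frame(read_id = rd$id, class = cls, discard_reason = reason,
                      score = b$score, pass_prefix = b$pass_prefix,
                      has_indel = b$has_indel, proto = b$proto,
                      stringsAsFactors = FALSE)
  al <- stats::aggregate(list(count = seq_len(n)),
                         by = list(sequence = rd$sequence, class = cls),
                         FUN = length)
  al <- al[order(-al$count), , drop = FALSE]
  rownames(al) <- NULL

  structure(list(outcome = outcome, calls = calls, alleles = al,
                 ref = ref, spec = spec, mode = mode), class = "sample_quant")
}

#' @export
print.sample_quant <- function(x, ...) {
  o <- x$outcome
  cat(sprintf("<sample_quant> %s (%s): %d reads, %d discarded\n",
              o$sample_id, o$mode, o$total_reads, o$n_discarded))
  cat(sprintf("  indel %.4f  sub %.4f  pe %.4f  background %.4f  tag %.4f\n",
              o$indel_freq, o$sub_freq, o$pe_freq, o$background_freq,
              o$tag_freq))
  invisible(x)
}

normalize_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    return(read_fastq(reads))
  if (is.character(reads)) {
    id <- names(reads)
    if (is.null(id)) id <- sprintf("read_%06d", seq_along(reads))
    return(list(id = id, sequence = unname(reads)))
  }
  if (is.list(reads) && !is.null(reads$sequence)) {
    id <- if (!is.null(reads$id)) reads$id
          else sprintf("read_%06d", seq_along(reads$sequence))
    return(list(id = id, sequence = reads$sequence))
  }
  stop("unsupported reads input", call. = FALSE)
}
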