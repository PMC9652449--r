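# Synthetic amplicon reads with ground truth, and simulated in vitro
# observations. Reads are single-end, anchored at the amplicon 5' end, so the
# prefix-identity filter applies directly. One outcome class is drawn per
# read from a categorical distribution; substitution edits are an overlay on
# otherwise-unedited reads. All randomness comes from one seeded stream,
# pre-drawn in fixed-size blocks that do not depend on the configured
# frequencies, which makes outputs byte-deterministic and class assignment
# monotone-nested in the class frequency.

# GUIDE-seq double-stranded oligodeoxynucleotide; its center 15-mer (offset
# 10) is the tag fragment counted by detect_dsodn_tag().
GUIDESEQ_DSODN <- "GTTTAATTGAGTTGTCATATGTTAATAACGGTAT"
DSODN_15MER_F <- "GTTGTCATATGTTAA"
DSODN_15MER_R <- "TTAACATATGACAAC"

#' Default indel length/placement profile for simulated reads
#'
#' Deletions and insertions of 1-10 bp with geometrically decaying length
#' weights and a start offset drawn uniformly from -2..+2 relative to the cut
#' site, emulating the tight clustering of repair-induced indels at the blunt
#' cut.
#'
#' @param p_deletion Probability that an indel is a deletion.
#' @param lengths,length_probs Candidate indel lengths and their weights.
#' @param offsets,offset_probs Candidate start offsets (bp relative to the
#'   cut site) and their weights.
#' @return Named list consumed by [read_sim_config()].
#' @export
indel_profile <- function(p_deletion = 0.6, lengths = 1:10,
                          length_probs = 0.55^(0:9),
                          offsets = -2:2, offset_probs = rep(1, 5)) {
  stopifnot(length(lengths) == length(length_probs),
            length(offsets) == length(offset_probs),
            all(lengths >= 1), all(lengths <= 20),
            all(abs(offsets) <= 2))
  list(p_deletion = p_deletion, lengths = as.integer(lengths),
       length_probs = length_probs / sum(length_probs),
       offsets = as.integer(offsets),
       offset_probs = offset_probs / sum(offset_probs))
}

#' Configuration for the read simulator
#'
#' @param amplicon An [amplicon_reference()].
#' @param n_reads Number of reads to simulate.
#' @param indel_freq Fraction of reads carrying a cut-site indel.
#' @param indel_prof Indel length/offset distribution, see [indel_profile()].
#' @param sub_edits Optional data frame of substitution edits with columns
#'   `position` (protospacer 1-20), `from`, `to`, `frequency`; applied
#'   independently per position to reads not assigned another class.
#' @param prime_edit Optional intended prime edit: list with `type`
#'   (`"insertion"` or `"deletion"`), `position` (0-based reference
#'   coordinate: inter-base insertion point, or first deleted base),
#'   `sequence` (inserted bases; ignored for deletions), `length` (deletion
#'   length), `frequency`.
#' @param background_indel_freq Fraction of reads carrying an indel other
#'   than the intended prime edit.
#' @param tag_freq Fraction of reads with a dsODN integration at the cut.
#' @param seq_error_rate Per-base substitution error probability.
#' @param read_len Read length in bases (>= 25).
#' @param seed Integer seed.
#' @return A validated `read_sim_config` object.
#' @export
read_sim_config <- function(amplicon, n_reads, indel_freq = 0,
                            indel_prof = indel_profile(), sub_edits = NULL,
                            prime_edit = NULL, background_indel_freq = 0,
                            tag_freq = 0, seq_error_rate = 0, read_len = 50L,
                            seed = 1L) {
  stopifnot(inherits(amplicon, "amplicon_ref"))
  n_reads <- as.integer(n_reads); read_len <- as.integer(read_len)
  if (n_reads < 1L) stop("n_reads must be positive", call. = FALSE)
  if (read_len < 25L)
    stop("read_len must be >= 25 (must span the filter prefix and the cut)",
         call. = FALSE)
  pe_freq <- if (is.null(prime_edit)) 0 else prime_edit$frequency
  fr <- c(indel_freq, pe_freq, background_indel_freq, tag_freq,
          seq_error_rate)
  if (any(fr < 0 | fr > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  if (indel_freq + pe_freq + background_indel_freq + tag_freq > 1 + 1e-12)
    stop("outcome class frequencies must sum to at most 1", call. = FALSE)
  maxdel <- max(c(20L, if (!is.null(prime_edit) &&
                           identical(prime_edit$type, "deletion"))
                        prime_edit$length))
  if (nchar(amplicon$sequence) < read_len + maxdel)
    stop("amplicon too short for the requested read length", call. = FALSE)
  if (read_len < amplicon$cut_site + 25L)
    stop("read_len must reach 25 bp past the cut site to span the dsODN tag",
         call. = FALSE)

  if (!is.null(sub_edits)) {
    sub_edits <- as.data.frame(sub_edits)
    stopifnot(all(c("position", "from", "to", "frequency") %in%
                    names(sub_edits)))
    if (any(sub_edits$position < 1 | sub_edits$position > 20))
      stop("sub_edits positions must lie in 1..20", call. = FALSE)
    idx <- protospacer_ref_index(amplicon, sub_edits$position)
    refb <- proto_base_at(amplicon, sub_edits$position)
    bad <- toupper(sub_edits$from) != refb
    if (any(bad))
      stop(sprintf("sub_edit source base mismatch at protospacer position %s: reference has %s",
                   paste(sub_edits$position[bad], collapse = ","),
                   paste(refb[bad], collapse = ",")), call. = FALSE)
    sub_edits$ref_index <- idx
    if (any(sub_edits$frequency < 0 | sub_edits$frequency > 1))
      stop("sub_edit frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(prime_edit)) prime_edit <- validate_prime_edit(prime_edit,
                                                              amplicon)

  structure(list(amplicon = amplicon, n_reads = n_reads,
                 indel_freq = indel_freq, indel_prof = indel_prof,
                 sub_edits = sub_edits, prime_edit = prime_edit,
                 background_indel_freq = background_indel_freq,
                 tag_freq = tag_freq, seq_error_rate = seq_error_rate,
                 read_len = read_len, seed = as.integer(seed)),
            class = "read_sim_config")
}

# base of the protospacer (non-targeted strand orientation) at positions p
proto_base_at <- function(ref, positions) {
  substring(ref$protospacer, positions, positions)
}

validate_prime_edit <- function(pe, amplicon) {
  stopifnot(is.list(pe), pe$type %in% c("insertion", "deletion"))
  refc <- strsplit(amplicon$sequence, "")[[1]]
  pos <- as.integer(pe$position)
  if (pe$type == "insertion") {
    seqv <- strsplit(toupper(pe$sequence), "")[[1]]
    if (!length(seqv) || !all(seqv %in% c("A", "C", "G", "T")))
      stop("prime edit insertion sequence must be ACGT", call. = FALSE)
    pe$length <- length(seqv)
    if (pos < 1L || pos > length(refc) - 1L)
      stop("prime edit insertion point outside the amplicon", call. = FALSE)
    if (seqv[length(seqv)] == refc[pos])
      stop("prime edit insertion is not in canonical left-aligned form; ",
           "shift it to the lowest reference coordinate", call. = FALSE)
  } else {
    pe$length <- as.integer(pe$length)
    if (pe$length < 1L) stop("deletion length must be >= 1", call. = FALSE)
    if (pos < 1L || pos + pe$length > length(refc))
      stop("prime edit deletion outside the amplicon", call. = FALSE)
    if (refc[pos] == refc[pos + pe$length])
      stop("prime edit deletion is not in canonical left-aligned form; ",
           "shift it to the lowest reference coordinate", call. = FALSE)
    pe$sequence <- ""
  }
  pe
}

# canonical (left-aligned) start of a deletion of length L at 0-based start s
canonical_del_start <- function(refc, s, L) {
  while (s > 0L && refc[s] == refc[s + L]) s <- s - 1L
  s
}

#' Simulate edited amplicon reads with a ground-truth table
#'
#' Each read is assigned one outcome class (cut-site indel, intended prime
#' edit, background indel, dsODN tag, or none) from a single categorical
#' draw; class-free reads then receive substitution edits independently per
#' configured position. Per-base sequencing error is applied last. Simulated
#' indels are placed so that their left-aligned coordinate falls inside the
#' +/-2 bp calling window, and indels drawn for the nuclease/background
#' classes are deterministically perturbed away from a configured intended
#' prime edit, so truth classes remain unambiguous under the calling rules.
#'
#' @param config A [read_sim_config()].
#' @return List with `id`, `sequence` (character vectors) and `truth`, a data
#'   frame with one row per read: `read_id`, `class` (`unedited`, `indel`,
#'   `intended_sub`, `intended_pe`, `background_indel`, `tag`), `indel_type`,
#'   `indel_len`, `indel_start` (canonical left-aligned, 0-based),
#'   `substitutions` (comma-separated protospacer positions),
#'   `tag_orientation`.
#' @export
simulate_edited_reads <- function(config) {
  stopifnot(inherits(config, "read_sim_config"))
  ref <- config$amplicon
  refseq <- ref$sequence
  refc <- strsplit(refseq, "")[[1]]
  n <- config$n_reads
  L_read <- config$read_len
  cut <- ref$cut_site
  prof <- config$indel_prof
  nsub <- if (is.null(config$sub_edits)) 0L else nrow(config$sub_edits)

  set.seed(config$seed)
  # fixed-size draw blocks (order matters; see module notes)
  u_class <- runif(n)
  u_orient <- runif(n)
  u_type <- runif(n)
  u_len <- runif(n)
  u_off <- runif(n)
  ins_mat <- matrix(c("A", "C", "G", "T")[ceiling(runif(n * 20L) * 4)], n)
  u_sub <- matrix(runif(n * max(1L, nsub)), n)
  u_err <- matrix(runif(n * L_read), n)
  u_errbase <- matrix(runif(n * L_read), n)

  pe <- config$prime_edit
  pe_freq <- if (is.null(pe)) 0 else pe$frequency
  breaks <- cumsum(c(config$indel_freq, pe_freq,
                     config$background_indel_freq, config$tag_freq))
  cls_idx <- findInterval(u_class, breaks, left.open = TRUE)
  classes <- c("indel", "intended_pe", "background_indel", "tag",
               "unedited")[cls_idx + 1L]

  len_draw <- prof$lengths[findInterval(u_len, cumsum(prof$length_probs),
                                        left.open = TRUE) + 1L]
  off_draw <- prof$offsets[findInterval(u_off, cumsum(prof$offset_probs),
                                        left.open = TRUE) + 1L]
  is_del <- u_type < prof$p_deletion

  reads <- rep(substr(refseq, 1L, L_read), n)
  truth <- data.frame(
    read_id = sprintf("read_%06d", seq_len(n)), class = classes,
    indel_type = NA_character_, indel_len = NA_integer_,
    indel_start = NA_integer_, substitutions = "",
    tag_orientation = NA_character_, stringsAsFactors = FALSE)

  ## cut-site indels (nuclease class) and background indels (prime-edit class)
  idx_indel <- which(classes %in% c("indel", "background_indel"))
  for (i in idx_indel) {
    cand <- resolve_indel(refc, cut, is_del[i], len_draw[i], off_draw[i],
                          ins_mat[i, ], prof, pe)
    if (cand$type == "deletion") {
      s <- cand$start
      reads[i] <- substr(paste0(substr(refseq, 1L, s),
                                substr(refseq, s + cand$len + 1L,
                                       nchar(refseq))), 1L, L_read)
    } else {
      p <- cand$start
      reads[i] <- substr(paste0(substr(refseq, 1L, p), cand$seq,
                                substr(refseq, p + 1L, nchar(refseq))),
                         1L, L_read)
    }
    truth$indel_type[i] <- cand$type
    truth$indel_len[i] <- cand$len
    truth$indel_start[i] <- cand$start
  }

  ## intended prime edits
  idx_pe <- which(classes == "intended_pe")
  if (length(idx_pe)) {
    if (pe$type == "insertion") {
      edited <- substr(paste0(substr(refseq, 1L, pe$position), pe$sequence,
                              substr(refseq, pe$position + 1L,
                                     nchar(refseq))), 1L, L_read)
    } else {
      edited <- substr(paste0(substr(refseq, 1L, pe$position),
                              substr(refseq, pe$position + pe$length + 1L,
                                     nchar(refseq))), 1L, L_read)
    }
    reads[idx_pe] <- edited
    truth$indel_type[idx_pe] <- pe$type
    truth$indel_len[idx_pe] <- pe$length
    truth$indel_start[idx_pe] <- pe$position
  }

  ## dsODN tag integrations (blunt, at the cut, either orientation)
  idx_tag <- which(classes == "tag")
  if (length(idx_tag)) {
    fwd <- u_orient[idx_tag] < 0.5
    oligo <- ifelse(fwd, GUIDESEQ_DSODN, revcomp(GUIDESEQ_DSODN))
    reads[idx_tag] <- substr(paste0(substr(refseq, 1L, cut), oligo,
                                    substr(refseq, cut + 1L, nchar(refseq))),
                             1L, L_read)
    truth$tag_orientation[idx_tag] <- ifelse(fwd, "+", "-")
    truth$indel_type[idx_tag] <- "insertion"
    truth$indel_len[idx_tag] <- nchar(GUIDESEQ_DSODN)
    truth$indel_start[idx_tag] <- cut
  }

  ## substitution overlay on class-free reads
  if (nsub > 0L) {
    free <- classes == "unedited"
    applied <- matrix(FALSE, n, nsub)
    for (j in seq_len(nsub)) {
      hit <- free & u_sub[, j] < config$sub_edits$frequency[j]
      if (any(hit)) {
        ridx <- config$sub_edits$ref_index[j] + 1L   # 1-based string index
        to <- toupper(config$sub_edits$to[j])
        # substitution is specified on the protospacer strand
        if (ref$strand == "-") to <- chartr("ACGTN", "TGCAN", to)
        substr(reads[hit], ridx, ridx) <- to
        applied[hit, j] <- TRUE
      }
    }
    nhit <- rowSums(applied)
    truth$substitutions[nhit > 0L] <- vapply(
      which(nhit > 0L),
      function(i) paste(config$sub_edits$position[applied[i, ]],
                        collapse = ","), character(1))
    truth$class[free & nhit == nsub] <- "intended_sub"
  }

  ## per-base sequencing error
  if (config$seq_error_rate > 0) {
    hits <- which(u_err < config$seq_error_rate, arr.ind = TRUE)
    if (nrow(hits)) {
      bases <- c("A", "C", "G", "T")
      for (h in seq_len(nrow(hits))) {
        i <- hits[h, 1L]; p <- hits[h, 2L]
        if (p > nchar(reads[i])) next
        cur <- substr(reads[i], p, p)
        alt <- setdiff(bases, cur)
        substr(reads[i], p, p) <-
          alt[ceiling(u_errbase[i, p] * length(alt))]
      }
    }
  }

  list(id = truth$read_id, sequence = reads, truth = truth, config = config)
}

# Deterministically resolve an indel draw to a placement whose left-aligned
# start lies inside the +/-2 bp window and, when an intended prime edit is
# configured, differs from it. No additional RNG draws are used.
resolve_indel <- function(refc, cut, is_del, len0, off0, ins_row, prof, pe) {
  offs <- unique(c(off0, prof$offsets))
  lens <- unique(c(len0, prof$lengths))
  if (is_del) {
    for (L in lens) {
      for (off in offs) {
        s <- cut + off
        if (s < 1L || s + L > length(refc)) next
        s_star <- canonical_del_start(refc, s, L)
        if (s_star < cut - 2L) next
        if (!is.null(pe) && pe$type == "deletion" &&
            pe$position == s_star && pe$length == L) next
        return(list(type = "deletion", start = s_star, len = L, seq = ""))
      }
    }
    stop("could not place a deletion with a left-aligned start inside the ",
         "cut-site window; amplicon context too repetitive", call. = FALSE)
  }
  for (L in lens) {
    for (off in offs) {
      p <- cut + off
      if (p < 1L || p > length(refc) - 1L) next
      seqv <- ins_row[seq_len(L)]
      if (seqv[L] == refc[p]) {
        # force canonical placement: last inserted base must differ from the
        # reference base 5' of the insertion point
        seqv[L] <- c(A = "C", C = "G", G = "T", T = "A")[refc[p]]
      }
      s <- paste(seqv, collapse = "")
      if (!is.null(pe) && pe$type == "insertion" && pe$position == p &&
          identical(pe$sequence, s)) {
        alt <- setdiff(c("A", "C", "G", "T"), c(seqv[L], refc[p]))[1]
        seqv[L] <- alt
        s <- paste(seqv, collapse = "")
      }
      return(list(type = "insertion", start = p, len = L, seq = s))
    }
  }
  stop("could not place an insertion inside the cut-site window",
       call. = FALSE)
}

#' Configuration for simulated cleavage kinetics
#'
#' @param tau Time constant in seconds (the fitted `k` is `1/tau`).
#' @param plateau Cleaved-fraction plateau in (0, 1].
#' @param times Sampling times in seconds, strictly increasing, positive.
#' @param noise_sd Gaussian noise SD added to fractions (clipped to [0, 1]).
#' @param active_fraction Active enzyme fraction in (0, 1] for titrations.
#' @param ratios Nominal protein:plasmid ratios, each in (0, 20].
#' @param seed Integer seed.
#' @return A validated `kin_sim_config` object.
#' @export
kin_sim_config <- function(tau = 30, plateau = 1, times = NULL,
                           noise_sd = 0, active_fraction = 1,
                           ratios = c(0.8, 1, 2, 4, 8, 12), seed = 1L) {
  stopifnot(tau > 0, plateau > 0, plateau <= 1, noise_sd >= 0,
            active_fraction >= 0, active_fraction <= 1)
  if (is.null(times)) times <- sampling_grid("medium")
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("times must be strictly increasing and positive", call. = FALSE)
  if (any(ratios <= 0 | ratios > 20))
    stop("ratios must lie in (0, 20]", call. = FALSE)
  structure(list(tau = tau, plateau = plateau, times = times,
                 noise_sd = noise_sd, active_fraction = active_fraction,
                 ratios = ratios, seed = as.integer(seed)),
            class = "kin_sim_config")
}

#' Simulate a cleavage time course
#'
#' Generates `cleaved(t) = plateau * (1 - exp(-t / tau))` plus Gaussian noise,
#' clipped to [0, 1]. With `noise_sd = 0` the exact curve is returned.
#'
#' @param config A [kin_sim_config()].
#' @return Data frame with columns `time`, `cleaved`.
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "kin_sim_config"))
  set.seed(config$seed)
  y <- config$plateau * (1 - exp(-config$times / config$tau))
  if (config$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, config$noise_sd)
  data.frame(time = config$times, cleaved = pmin(pmax(y, 0), 1))
}

#' Simulate a single-turnover titration series
#'
#' Under single turnover and random enzyme-substrate partitioning, the intact
#' plasmid fraction at nominal protein:plasmid ratio `r` is
#' `exp(-active_fraction * r)`. Gaussian noise is added and clipped to [0, 1].
#'
#' @param config A [kin_sim_config()].
#' @return Data frame with columns `ratio`, `intact`.
#' @export
simulate_titration <- function(config) {
  stopifnot(inherits(config, "kin_sim_config"))
  set.seed(config$seed)
  y <- exp(-config$active_fraction * config$ratios)
  if (config$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, config$noise_sd)
  data.frame(ratio = config$ratios, intact = pmin(pmax(y, 0), 1))
}

#' Assemble a GUIDE-seq-style per-site read-count table
#'
#' Validates a desk-scale site table (one on-target site, positive total
#' reads), annotates per-site mismatch counts against the target spacer, and
#' attaches totals. This is the input hook for [guideseq_specificity()].
#'
#' @param target The 20-nt target (protospacer) sequence.
#' @param sites Data frame with columns `sequence`, `reads`, `on_target`.
#' @return The annotated site table with a `mismatches` column and attributes
#'   `total_reads` and `target`.
#' @export
simulate_guideseq_readset <- function(target, sites) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("sequence", "reads", "on_target") %in% names(sites)))
  if (sum(sites$on_target) != 1L)
    stop("exactly one site must be flagged on-target", call. = FALSE)
  if (sum(sites$reads) <= 0)
    stop("total read count must be positive", call. = FALSE)
  sites$mismatches <- vapply(sites$sequence, function(s)
    mismatch_filter(s, target)$mismatches, integer(1), USE.NAMES = FALSE)
  attr(sites, "total_reads") <- sum(sites$reads)
  attr(sites, "target") <- target
  sites
}
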