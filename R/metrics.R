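# Derived activity/specificity statistics: off/on ratios, normalisation to a
# reference variant, base-editing window vs bystander partitions, reporting
# filters, and desk-scale GUIDE-seq metrics.

#' Off-target/on-target activity ratio
#'
#' @param off,on Activity fractions (vectorised).
#' @return `off/on`; `NA` with a `"reason"` attribute where `on` is 0.
#' @export
off_on_ratio <- function(off, on) {
  stopifnot(length(off) == length(on) || length(off) == 1L || length(on) == 1L)
  out <- ifelse(on > 0, off / on, NA_real_)
  if (anyNA(out)) attr(out, "reason") <- "on-target activity is zero"
  out
}

#' Normalise a variant's activity to a reference measurement
#'
#' Per-pair definition: each variant value is divided by its own paired
#' reference value (e.g. a 21G-sgRNA measurement by its 20G-sgRNA
#' counterpart, or a high-fidelity variant by wild type on the same target).
#' Values may exceed 1.
#'
#' @param variant,reference Activity fractions (vectorised, paired).
#' @return `variant/reference`; `NA` with a reason where `reference` is 0.
#' @export
normalize_activity <- function(variant, reference) {
  out <- ifelse(reference > 0, variant / reference, NA_real_)
  if (anyNA(out)) attr(out, "reason") <- "reference activity is zero"
  out
}

#' Median and interquartile range
#'
#' Quantiles use the linear-interpolation convention (R type 7).
#'
#' @param values Numeric vector (length >= 1).
#' @return List with `median`, `q1`, `q3`, `n`.
#' @export
summarize_median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarise", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(values))
}

#' Build a per-position base-editing profile
#'
#' For every protospacer position 1-20 reports the fraction of reads carrying
#' the editor's transition (A->G for ABE, C->T for CBE) at that position,
#' among non-indel reads passing the prefix filter (the denominator can be
#' switched to all passing reads). Positions are flagged as inside or outside
#' the editing window.
#'
#' @param quant A `sample_quant` from [quantify_sample()].
#' @param target_base `"A"` (ABE) or `"C"` (CBE).
#' @param window Inclusive protospacer position range of the editing window.
#' @param denominator `"non_indel"` (default, consistent with the intended-
#'   modification formula) or `"all"` (all passing reads).
#' @return Data frame of class `base_edit_profile` with columns `position`,
#'   `ref_base`, `edited_base`, `n_reads`, `edited_fraction`, `is_target`,
#'   `in_window`.
#' @export
base_edit_profile <- function(quant, target_base = c("A", "C"),
                              window = c(4L, 8L),
                              denominator = c("non_indel", "all")) {
  stopifnot(inherits(quant, "sample_quant"))
  target_base <- match.arg(target_base)
  denominator <- match.arg(denominator)
  edited_base <- unname(c(A = "G", C = "T")[target_base])
  calls <- quant$calls
  keep <- calls$class != "discarded" & !is.na(calls$proto)
  if (denominator == "non_indel") keep <- keep & !calls$has_indel
  proto <- calls$proto[keep]
  refb <- strsplit(quant$ref$protospacer, "")[[1]]
  frac <- nr <- numeric(20)
  for (p in 1:20) {
    obs <- substr(proto, p, p)
    covered <- obs %in% c("A", "C", "G", "T")
    nr[p] <- sum(covered)
    frac[p] <- if (nr[p] > 0) mean(obs[covered] == edited_base) else NA_real_
  }
  # only transitions away from the target base are editing; at other
  # reference bases the fraction is reported but is not a target position
  structure(data.frame(position = 1:20, ref_base = refb,
                       edited_base = edited_base, n_reads = as.integer(nr),
                       edited_fraction = ifelse(refb == target_base, frac,
                                                NA_real_),
                       is_target = refb == target_base,
                       in_window = 1:20 >= window[1] & 1:20 <= window[2],
                       stringsAsFactors = FALSE),
            class = c("base_edit_profile", "data.frame"))
}

#' Partition a base-editing profile into window and bystander positions
#'
#' Target-base positions inside the editing window (default protospacer 4-8)
#' versus all other target-base positions (bystanders). Returns the raw
#' per-position edited fractions plus median/IQR summaries.
#'
#' @param profile A `base_edit_profile` (or any data frame with `position`,
#'   `edited_fraction`, `is_target` columns).
#' @param window Inclusive protospacer position range.
#' @return List with `window` and `bystander`, each holding `positions`,
#'   `values` and `summary` (median/IQR); `window_empty` is `TRUE` when no
#'   target base falls inside the window.
#' @export
window_vs_bystander <- function(profile, window = c(4L, 8L)) {
  df <- as.data.frame(profile)
  stopifnot(all(c("position", "edited_fraction", "is_target") %in% names(df)))
  tgt <- df[df$is_target, , drop = FALSE]
  inw <- tgt$position >= window[1] & tgt$position <= window[2]
  mk <- function(x) {
    if (!nrow(x)) return(list(positions = integer(), values = numeric(),
                              summary = NULL))
    list(positions = x$position, values = x$edited_fraction,
         summary = summarize_median_iqr(x$edited_fraction))
  }
  out <- list(window = mk(tgt[inw, , drop = FALSE]),
              bystander = mk(tgt[!inw, , drop = FALSE]),
              window_empty = !any(inw))
  if (out$window_empty)
    warning("no target base inside the editing window", call. = FALSE)
  out
}

#' Select the on-target base position from a reference variant's profile
#'
#' For off-target/on-target comparisons the on-target value is taken at the
#' target-base position edited at the highest level by a designated reference
#' editor variant. Ties are broken by the smallest protospacer position.
#'
#' @param profiles Named list of `base_edit_profile`s, one per variant.
#' @param reference_variant Name of the designated reference variant.
#' @return The selected protospacer position (integer).
#' @export
select_on_target_adenine <- function(profiles, reference_variant) {
  if (!reference_variant %in% names(profiles))
    stop("reference variant profile not found: ", reference_variant,
         call. = FALSE)
  p <- as.data.frame(profiles[[reference_variant]])
  tgt <- p[p$is_target & !is.na(p$edited_fraction), , drop = FALSE]
  if (!nrow(tgt))
    stop("no target-base positions in the reference profile", call. = FALSE)
  best <- max(tgt$edited_fraction)
  min(tgt$position[tgt$edited_fraction == best])
}

#' Apply the reporting filters to a table of activity records
#'
#' Retains records whose on-target activity strictly exceeds
#' `on_target_threshold` (a value exactly at the threshold is excluded), and
#' separately flags records whose editing is below `min_edit`. Every
#' exclusion is logged with a rule identifier.
#'
#' @param records Data frame with an `on_target` column (fractions); an
#'   optional `editing` column feeds the low-editing flag.
#' @param on_target_threshold Strict lower bound on on-target activity.
#' @param min_edit Threshold under which editing is flagged as low.
#' @return List with `retained`, `excluded`, `exclusion_log` (data frame of
#'   `row`, `rule`, `value`) and `low_editing` (logical vector over retained
#'   and excluded alike).
#' @export
apply_reporting_filters <- function(records, on_target_threshold = 0.70,
                                    min_edit = 0.05) {
  records <- as.data.frame(records)
  stopifnot("on_target" %in% names(records))
  keep <- records$on_target > on_target_threshold
  log <- data.frame(row = which(!keep), rule = "on_target_not_exceeding",
                    value = records$on_target[!keep],
                    stringsAsFactors = FALSE)
  low <- rep(NA, nrow(records))
  if ("editing" %in% names(records)) {
    low <- records$editing < min_edit
    log <- rbind(log, data.frame(row = which(low), rule = "low_editing",
                                 value = records$editing[low],
                                 stringsAsFactors = FALSE))
  }
  list(retained = records[keep, , drop = FALSE],
       excluded = records[!keep, , drop = FALSE],
       exclusion_log = log, low_editing = low)
}

#' Mismatch filter for candidate off-target sites
#'
#' Hamming distance between a candidate site and the target spacer; the site
#' is retained iff the distance is at most `max_mm` (default: at most seven
#' mismatches).
#'
#' @param candidate,target Equal-length DNA strings (ACGT).
#' @param max_mm Maximum number of mismatches retained.
#' @return List with `mismatches` (integer) and `retain` (logical).
#' @export
mismatch_filter <- function(candidate, target, max_mm = 7L) {
  candidate <- toupper(candidate); target <- toupper(target)
  if (nchar(candidate) != nchar(target))
    stop("candidate and target must have equal length", call. = FALSE)
  if (!grepl("^[ACGT]+$", candidate) || !grepl("^[ACGT]+$", target))
    stop("sequences must contain only ACGT", call. = FALSE)
  a <- strsplit(candidate, "")[[1]]
  b <- strsplit(target, "")[[1]]
  mm <- sum(a != b)
  list(mismatches = as.integer(mm), retain = mm <= max_mm)
}

#' On-target cleavage specificity from a per-site read-count table
#'
#' Specificity is the percentage of on-target reads among all reads across
#' retained sites; the off-target site count is the number of sites minus the
#' single on-target site.
#'
#' @param site_counts Data frame with `reads` and `on_target` columns (e.g.
#'   from [simulate_guideseq_readset()]).
#' @return List with `specificity_pct`, `on_reads`, `total_reads`,
#'   `off_target_sites`.
#' @export
guideseq_specificity <- function(site_counts) {
  sc <- as.data.frame(site_counts)
  stopifnot(all(c("reads", "on_target") %in% names(sc)))
  if (sum(sc$on_target) != 1L)
    stop("exactly one site must be flagged on-target", call. = FALSE)
  total <- sum(sc$reads)
  if (total <= 0) stop("total read count is zero", call. = FALSE)
  on <- sum(sc$reads[sc$on_target])
  list(specificity_pct = 100 * on / total, on_reads = on,
       total_reads = total, off_target_sites = nrow(sc) - 1L)
}
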