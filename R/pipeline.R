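# Reproducible end-to-end runs from one flat configuration: simulate
# (optional) -> align -> call -> metrics, or kinetics fits, with a
# machine-readable manifest. Every analysis threshold is surfaced as a named
# config key with the standard amplicon-NGS defaults (prefix 20 bp at 75%
# identity, +/-2 bp indel window, editing window 4-8, 70% on-target
# reporting filter, 5% low-editing flag, 7-mismatch retention).

run_config_defaults <- function() {
  list(mode = "simulate", out_dir = "crisprquant_out", seed = 1L,
       # inputs
       fastq = NULL, amplicon_fasta = NULL, amplicon_annotation = NULL,
       amplicon_name = NULL, timecourse_tsv = NULL, titration_tsv = NULL,
       # simulation
       n_reads = 2000L, indel_freq = 0.1, tag_freq = 0, pe_freq = 0,
       background_indel_freq = 0, sub_position = NULL, sub_from = NULL,
       sub_to = NULL, sub_freq = NULL, pe_type = NULL, pe_position = NULL,
       pe_sequence = NULL, pe_length = NULL, seq_error_rate = 0,
       read_len = 50L,
       # calling / metrics thresholds
       call_mode = "all", prefix_len = 20L, min_frac = 0.75, window_bp = 2L,
       window_start = 4L, window_end = 8L, on_target_threshold = 0.70,
       min_edit = 0.05, max_mm = 7L,
       strict_indel_read = FALSE, count_discarded = FALSE,
       fix_plateau = FALSE, plasmid_conc = 6.2)
}

#' Read and validate a run configuration
#'
#' Configurations are flat YAML key-value files; unknown keys are rejected
#' and threshold ranges are validated with the offending field named in the
#' error.
#'
#' @param path YAML file, or a named list of overrides.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    yaml::read_yaml(path)
  }
  base <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(base, cfg)

  chk <- function(cond, field, msg) {
    if (!cond) stop(sprintf("config field '%s' invalid: %s", field, msg),
                    call. = FALSE)
  }
  chk(cfg$mode %in% c("simulate", "nuclease", "base_editor", "prime_editor",
                      "tag", "all", "kinetics"),
      "mode", "must be one of simulate/nuclease/base_editor/prime_editor/tag/all/kinetics")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed",
      "must be an integer")
  chk(cfg$prefix_len >= 1 && cfg$prefix_len <= 100, "prefix_len",
      "must lie in 1..100")
  chk(cfg$min_frac > 0 && cfg$min_frac <= 1, "min_frac",
      "must lie in (0, 1]")
  chk(cfg$window_bp >= 0 && cfg$window_bp <= 10, "window_bp",
      "must lie in 0..10")
  chk(cfg$window_start >= 1 && cfg$window_end <= 20 &&
        cfg$window_start <= cfg$window_end, "window_start",
      "editing window must lie within 1..20")
  chk(cfg$on_target_threshold > 0 && cfg$on_target_threshold < 1,
      "on_target_threshold", "must lie in (0, 1)")
  chk(cfg$min_edit >= 0 && cfg$min_edit < 1, "min_edit",
      "must lie in [0, 1)")
  chk(cfg$max_mm >= 0 && cfg$max_mm <= 20, "max_mm", "must lie in 0..20")
  chk(cfg$n_reads >= 1, "n_reads", "must be positive")
  chk(cfg$read_len >= 25, "read_len", "must be >= 25")
  for (f in c("indel_freq", "tag_freq", "pe_freq", "background_indel_freq",
              "seq_error_rate"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must lie in [0, 1]")
  for (f in c("fastq", "amplicon_fasta", "amplicon_annotation",
              "timecourse_tsv", "titration_tsv"))
    if (!is.null(cfg[[f]]))
      chk(file.exists(cfg[[f]]), f, paste("path not resolvable:", cfg[[f]]))
  structure(cfg, class = "run_config")
}

pipeline_amplicon <- function(cfg) {
  if (is.null(cfg$amplicon_fasta) || is.null(cfg$amplicon_annotation))
    stop("config fields 'amplicon_fasta' and 'amplicon_annotation' are ",
         "required for read analysis modes", call. = FALSE)
  amps <- read_amplicons(cfg$amplicon_fasta, cfg$amplicon_annotation)
  nm <- cfg$amplicon_name %||% names(amps)[1]
  if (!nm %in% names(amps))
    stop("amplicon '", nm, "' not found in annotation", call. = FALSE)
  amps[[nm]]
}

pipeline_spec <- function(cfg, ref) {
  subs <- NULL
  if (!is.null(cfg$sub_position))
    subs <- data.frame(position = as.integer(cfg$sub_position),
                       from = cfg$sub_from, to = cfg$sub_to,
                       stringsAsFactors = FALSE)
  pe <- NULL
  if (!is.null(cfg$pe_type))
    pe <- list(type = cfg$pe_type, position = as.integer(cfg$pe_position),
               sequence = cfg$pe_sequence %||% "",
               length = cfg$pe_length %||% nchar(cfg$pe_sequence %||% ""))
  if (is.null(subs) && is.null(pe)) return(NULL)
  edit_spec(ref, substitutions = subs, intended_indel = pe,
            window = c(cfg$window_start, cfg$window_end))
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate (optional) -> align -> call -> outcome tables, or the
#' kinetics fits, writing TSV outputs plus a machine-readable run manifest
#' (config echo, package/R versions, seed, per-stage counts) into
#' `out_dir`. Identical config and seed reproduce byte-identical outputs.
#'
#' @param config Path to a YAML config or a named list (see
#'   [read_run_config()]).
#' @return Named list of output file paths, invisibly; the manifest path is
#'   always included.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  manifest <- list(config = cfg[order(names(cfg))],
                   package = "crisprquant",
                   package_version = as.character(utils::packageVersion("crisprquant")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = cfg$seed)

  if (cfg$mode == "kinetics") {
    if (is.null(cfg$timecourse_tsv) && is.null(cfg$titration_tsv))
      stop("kinetics mode requires 'timecourse_tsv' and/or 'titration_tsv'",
           call. = FALSE)
    if (!is.null(cfg$timecourse_tsv)) {
      tc <- read_tsv_checked(cfg$timecourse_tsv, c("time", "cleaved"))
      reps <- if ("replicate" %in% names(tc)) split(tc, tc$replicate)
              else list(`1` = tc)
      fits <- lapply(reps, fit_one_phase_decay,
                     fix_plateau = isTRUE(cfg$fix_plateau))
      rpt <- data.frame(
        replicate = names(fits),
        k = vapply(fits, `[[`, numeric(1), "k"),
        tau = vapply(fits, `[[`, numeric(1), "tau"),
        plateau = vapply(fits, `[[`, numeric(1), "plateau"),
        sse = vapply(fits, `[[`, numeric(1), "sse"),
        converged = vapply(fits, `[[`, logical(1), "converged"),
        category = vapply(fits, function(f)
          choose_sampling_category(max(f$k, 0))$category, character(1)),
        stringsAsFactors = FALSE)
      out$kinetics_fits <- file.path(cfg$out_dir, "kinetics_fits.tsv")
      write_tsv(rpt, out$kinetics_fits)
      manifest$n_timecourses <- length(fits)
    }
    if (!is.null(cfg$titration_tsv)) {
      ti <- read_tsv_checked(cfg$titration_tsv, c("ratio", "intact"))
      fit <- estimate_active_fraction(ti, plasmid_conc = cfg$plasmid_conc)
      rpt <- data.frame(active_fraction = fit$active_fraction,
                        raw_a = fit$raw_a, sse = fit$sse,
                        no_activity = fit$no_activity)
      out$titration_fit <- file.path(cfg$out_dir, "titration_fit.tsv")
      write_tsv(rpt, out$titration_fit)
    }
  } else {
    ref <- pipeline_amplicon(cfg)
    spec <- pipeline_spec(cfg, ref)
    if (cfg$mode == "simulate") {
      sub_edits <- if (!is.null(spec) && !is.null(spec$substitutions)) {
        se <- spec$substitutions
        se$frequency <- rep_len(cfg$sub_freq %||% 0, nrow(se))
        se
      } else NULL
      pe_sim <- if (!is.null(spec) && !is.null(spec$intended_indel)) {
        pe <- spec$intended_indel; pe$frequency <- cfg$pe_freq; pe
      } else NULL
      sim <- simulate_edited_reads(read_sim_config(
        ref, n_reads = cfg$n_reads, indel_freq = cfg$indel_freq,
        sub_edits = sub_edits, prime_edit = pe_sim,
        background_indel_freq = cfg$background_indel_freq,
        tag_freq = cfg$tag_freq, seq_error_rate = cfg$seq_error_rate,
        read_len = cfg$read_len, seed = cfg$seed))
      out$fastq <- file.path(cfg$out_dir, "reads.fastq")
      write_fastq(sim, out$fastq)
      out$truth <- file.path(cfg$out_dir, "truth.tsv")
      write_tsv(sim$truth, out$truth)
      reads <- sim
      call_mode <- cfg$call_mode
      manifest$n_reads_simulated <- length(sim$sequence)
    } else {
      if (is.null(cfg$fastq))
        stop("config field 'fastq' is required in analysis modes",
             call. = FALSE)
      reads <- read_fastq(cfg$fastq)
      call_mode <- cfg$mode
    }
    q <- quantify_sample(reads, ref, spec = spec, mode = call_mode,
                         sample_id = ref$name,
                         prefix_len = cfg$prefix_len,
                         min_frac = cfg$min_frac, window_bp = cfg$window_bp,
                         strict_indel_read = isTRUE(cfg$strict_indel_read),
                         count_discarded = isTRUE(cfg$count_discarded))
    out$outcome <- file.path(cfg$out_dir, "outcome.tsv")
    write_tsv(q$outcome, out$outcome)
    out$calls <- file.path(cfg$out_dir, "calls.tsv")
    write_tsv(q$calls, out$calls)
    out$alleles <- file.path(cfg$out_dir, "alleles.tsv")
    write_tsv(q$alleles, out$alleles)
    if (!is.null(spec) && !is.null(spec$substitutions)) {
      prof <- base_edit_profile(q,
                                target_base = toupper(spec$substitutions$from[1]),
                                window = c(cfg$window_start, cfg$window_end))
      out$profile <- file.path(cfg$out_dir, "base_edit_profile.tsv")
      write_tsv(as.data.frame(prof), out$profile)
    }
    manifest$counts <- as.list(q$outcome[1, c("total_reads", "n_discarded",
                                              "n_unedited", "n_indel",
                                              "n_intended_sub",
                                              "n_intended_pe",
                                              "n_background_indel", "n_tag")])
  }

  out$manifest <- file.path(cfg$out_dir, "manifest.json")
  manifest$outputs <- lapply(out, basename)
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(out)
}

#' Demo run configuration
#'
#' Returns the shipped end-to-end demo configuration (simulate -> align ->
#' call on the demo amplicon) with package-resolved input paths.
#'
#' @param out_dir Output directory.
#' @param seed Seed override.
#' @return A validated `run_config`.
#' @export
demo_run_config <- function(out_dir = file.path(tempdir(), "crisprquant_demo"),
                            seed = NULL) {
  dir <- system.file("extdata", package = "crisprquant")
  cfg <- yaml::read_yaml(file.path(dir, "demo_config.yaml"))
  cfg$amplicon_fasta <- file.path(dir, cfg$amplicon_fasta)
  cfg$amplicon_annotation <- file.path(dir, cfg$amplicon_annotation)
  cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- seed
  read_run_config(cfg)
}
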