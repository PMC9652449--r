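---
title: "Quantifying CRISPR editing outcomes and cleavage kinetics with crisprquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR editing outcomes and cleavage kinetics with crisprquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprquant)
```

## Scope and model

`crisprquant` quantifies genome-editing outcomes from amplicon
deep-sequencing reads and estimates in vitro cleavage kinetics for
SpCas9-family nucleases, base editors and prime editors. The package covers
the desk-scale quantification layer of such experiments: it does not map
reads genome-wide, consolidate UMIs, or perform the significance testing
that is routinely done downstream (repeated-measures ANOVA and post-hoc
tests are deliberately out of scope).

The coordinate conventions are fixed throughout:

* Protospacer positions are numbered 1–20 in the 5'→3' direction on the
  **non-targeted strand** (the strand whose sequence equals the spacer).
* The blunt SpCas9 cut site is **derived**, never user-set: it is the
  inter-base bond between protospacer positions 17 and 18, i.e. 3 bp 5' of
  the NGG PAM. Internally all coordinates are 0-based with inter-base cut
  coordinates; user-facing reports use 1-based protospacer positions.

## Read filtering and outcome classes

Reads are aligned to their reference amplicon and pass through two rules
before classification:

1. **Prefix identity**: a read is kept iff at least 75% of the first 20
   reference bases are covered by match columns (threshold 15/20;
   mismatched and deletion-covered positions count as unmatched). Both the
   prefix length and the fraction are configurable.
2. **Indel window**: an indel is attributed to the cut iff its left-aligned
   reference start (first deleted base, or inter-base insertion point) lies
   within ±2 bp of the cut coordinate.

Per-sample frequencies are ratios of per-class read counts to the total:

* indel frequency = reads with a cut-site indel / total reads;
* base-edit frequency = reads with the intended substitution(s) and **no
  indel anywhere** / total reads;
* prime-edit frequency = reads whose indel content is **exactly** the
  intended insertion or deletion / total reads, with the indel background
  counted from reads whose indels differ from the aimed edit;
* tag frequency = reads containing the dsODN center 15-mer
  (`GTTGTCATATGTTAA` or its reverse complement) as an exact substring.

Two points in these rules are genuinely ambiguous in the conventions the
package follows, and both behaviours are implemented:

* *"Indels without mismatches"* is read as: the indel event itself consists
  of pure insertion/deletion alignment operations, and distal mismatches
  elsewhere in the read do not veto the call. The stricter reading — the
  entire read must be mismatch-free — is available as
  `strict_indel_read = TRUE`.
* The frequency denominator is taken as the reads passing the prefix
  filter (the filter defines which reads are "aligned" at all);
  `count_discarded = TRUE` switches to raw read totals.

## Alignment

Reads are short PCR products, so the aligner is a fitting (semiglobal)
affine-gap alignment of the whole read against the amplicon: reference
overhang is free, the read is consumed end to end. Default scoring is match
+1, mismatch −4, gap open −6, gap extend −1 (a length-L gap costs
−6 − L). These defaults make one clean indel near the cut cheaper than the
scattered mismatches that would otherwise mimic it, which matches the
one-indel-event read model of editing amplicons; they are configurable via
`alignment_scoring()`. Equal-scoring indel placements are canonicalised by
left-alignment (lowest reference coordinate), which makes the ±2 bp window
test deterministic. Read orientation is decided by alignment score of the
two orientations; an unambiguous prefix-identity screen skips the second
dynamic-programming pass for speed. Ties prefer the forward orientation and
aligned columns over gaps.

Optimality is validated against `align_score_exhaustive()`, an independent
formulation that maximises over whole gap runs (and adjacent
insertion+deletion run pairs) rather than Gotoh state matrices; the two
must agree exactly on randomized small instances, and applying the
alignment to the reference must regenerate every read byte-for-byte.

## The synthetic read generator

`simulate_edited_reads()` emulates single-end amplicon reads anchored at
the amplicon 5' end (real data are often 2×150 paired-end; merging is out
of scope, and the single-end model keeps the prefix filter directly
applicable). Each read draws **one** outcome class from a categorical
distribution (cut-site indel, intended prime edit, background indel, dsODN
tag, or none); class-free reads then receive substitution edits
independently per configured position, and i.i.d. per-base substitution
error is applied last. Design choices that matter for interpretation:

* Indel lengths default to 1–10 bp with geometrically decaying weights,
  60% deletions, start offsets uniform on −2..+2 — a simple caricature of
  repair outcomes, not a learned indel spectrum.
* Simulated indels are placed so that their **left-aligned** coordinate
  falls inside the calling window, with deterministic adjustment of the
  offset/length/last-inserted-base; without this, a deletion drawn at the
  window edge inside a repeat could left-align out of the window and the
  truth table would disagree with a correct caller.
* The dsODN is modelled as a blunt 34-bp insertion exactly at the cut, in
  either orientation with probability 0.5; only its center 15-mer matters
  downstream.
* Sequencing error is substitution-only. Real sequencers also produce
  indel errors, quality gradients and PCR artefacts; passing recovery
  tests on this generator therefore demonstrates correctness of the
  quantification rules, not robustness to every real-data failure mode.
* All randomness comes from one seeded stream, pre-drawn in fixed-size
  blocks that do not depend on the configured frequencies. This makes
  output byte-deterministic and class assignment monotone-nested in the
  class frequency (raising `indel_freq` with the same seed can only add
  indel reads, never remove them).

```{r}
ref <- amplicon_reference(
  "demo_site",
  "ATGCCGCTCACTGATCAGCTACGTCTGGCATCGTACGATCGTTAGCATGCACGTTCAGATCGGATACGTC",
  protospacer_start = 5, strand = "+", pam = "NGG")
sim <- simulate_edited_reads(read_sim_config(
  ref, n_reads = 1000, indel_freq = 0.25, tag_freq = 0.05,
  sub_edits = data.frame(position = 5, from = "A", to = "G",
                         frequency = 0.2),
  seq_error_rate = 0.001, seed = 42))
spec <- edit_spec(ref, substitutions = data.frame(position = 5, from = "A",
                                                  to = "G"))
q <- quantify_sample(sim, ref, spec = spec, mode = "all")
q$outcome[c("n_indel", "n_intended_sub", "n_tag", "indel_freq", "sub_freq",
            "tag_freq")]
```

## Base-editing profiles and derived metrics

`base_edit_profile()` reports, per protospacer position, the fraction of
reads carrying the editor's transition (A→G or C→T) among non-indel
passing reads — the denominator matching the "without indels" convention
of the base-edit frequency; `denominator = "all"` switches to all passing
reads. `window_vs_bystander()` partitions target-base positions into the
editing window (default positions 4–8) versus bystanders and summarises
both with median/IQR. Quantiles use the linear-interpolation convention
(R type 7) throughout, a fixed choice since graphing software conventions
differ.

Specificity metrics are deliberately small functions: `off_on_ratio()`
(undefined when on-target activity is zero, reported as missing with a
reason), `normalize_activity()` (per-pair normalisation — the tests include
a cohort where normalising medians would give a different answer),
`mismatch_filter()` (Hamming distance, retain at ≤7 mismatches),
`guideseq_specificity()` (on-target reads as a percentage of all reads) and
`apply_reporting_filters()`. The reporting filter treats "exceeded 70%" as
a strict inequality — a record at exactly 0.70 is excluded — and flags
editing below 5% separately; both boundaries are unit-tested.
`select_on_target_adenine()` picks the target-base position maximally
edited by a designated reference editor variant, breaking ties toward the
smallest position (ties are a package decision; real profiles rarely tie).

## Kinetics

Cleavage time courses follow a one-phase exponential rise to plateau,
`cleaved(t) = P (1 − e^{−t/τ})`, with rate constant `k = 1/τ` (s⁻¹).
`fit_one_phase_decay()` uses Levenberg–Marquardt least squares with
deterministic multi-start: τ₀ from the time at half-plateau, P₀ from the
last observation, plus scaled variants of τ₀; the reported fit never has a
larger SSE than its initialisation. The plateau is fitted (bounded to
(0, 1.05]) because incomplete cleavage is real for low-activity variants;
`fix_plateau = TRUE` reproduces the constrained fit. Fits whose τ falls
outside the sampled time range are flagged `poorly_constrained` — the
signature of a sampling-category mismatch. Sampling grids are log-spaced
within the fast (3–30 s), medium (3–300 s) and slow (3–3600 s) categories,
and `choose_sampling_category()` picks the narrowest category spanning
roughly three time constants. All-zero traces return a no-activity
sentinel (`k = 0`, `τ = Inf`); for all other fits `k·τ = 1` holds exactly.

For active-enzyme titrations the package formalises the single-turnover
("one-fold turnover") argument as random partitioning of enzyme over
substrate molecules: at nominal enzyme:plasmid ratio `r` the number of
active complexes attacking a given plasmid is Poisson with mean `a·r`, so
the intact fraction is `intact(r) = e^{−a·r}` and `a` is the active
fraction of the nominal enzyme amount. The curve family is the stated
convention; the mechanistic mapping from ratio series to that family is
this package's own formalisation, so the raw fitted parameter is always
reported alongside the clamped active fraction. A titration whose intact
fraction rises with enzyme dose is rejected as a data-quality error.
`threefold_excess_check()` verifies the 1:3 plasmid:active-protein design
ratio within ±10% (a documented tolerance choice).

```{r}
tc <- simulate_timecourse(kin_sim_config(tau = 50,
                                         times = sampling_grid("medium"),
                                         noise_sd = 0.02, seed = 1))
fit_one_phase_decay(tc)
ti <- simulate_titration(kin_sim_config(active_fraction = 0.6,
                                        noise_sd = 0.02, seed = 1))
estimate_active_fraction(ti, nominal_conc = 31)
```

## Reproducible runs

`run_pipeline()` executes simulate → align → call → tables (or the
kinetics fits) from one flat YAML configuration in which every analysis
threshold is a named key defaulting to the conventions above (0.75/20 bp
prefix rule, ±2 bp window, window 4–8, 70% and 5% reporting thresholds, 7
mismatches). Outputs are TSVs plus a JSON manifest echoing the full
configuration, seed and per-stage counts; identical configuration and seed
reproduce byte-identical outputs. The shipped demo configuration
(`demo_run_config()`) is the end-to-end smoke test.

## Validation strategy and problem sizes

The test suite validates each rule at its boundary (15/20 vs 14/20 prefix
matches, cut±2 vs cut±3 indel starts, 7 vs 8 mismatches, 0.70 vs 0.71
on-target activity), checks per-read classification against the simulator
truth table with zero tolerated discordance on error-free reads, and runs
recovery studies at sizes chosen to keep the suite fast while leaving
binomial/Monte-Carlo bands tight: read sets of n = 2000 on a 70-bp
amplicon with 50-bp reads, 200 seeded replicates per frequency channel,
500 randomized alignment-optimality cases, and 100 kinetics replicates per
time constant (τ ∈ {5, 50, 500} s at 2% noise; titrations at active
fractions 0.3/0.6/1.0). `scripts/acceptance.R` recomputes the same
quantities from scratch at moderately reduced replicate counts and writes
them as JSON.

## Known limitations

* Single-end, 5'-anchored reads only; no paired-end merging, no
  quality-aware trimming, no chimera detection.
* The aligner targets short amplicons; it is not a genome mapper and makes
  no mapping-quality claims, and equivalence with any external aligner's
  scoring is not promised.
* The indel spectrum, error model and dsODN integration geometry of the
  simulator are deliberately simple caricatures (see above).
* Editing fractions at heavily deleted positions are computed over covered
  reads only; amplicons with long repeats near the cut can make the ±2 bp
  window genuinely ill-posed, and the simulator refuses such contexts
  rather than guessing.
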