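# crisprquant

Quantification of CRISPR editing outcomes from amplicon deep sequencing,
plus in vitro cleavage kinetics, in R.

When a nuclease, base editor or prime editor is characterised by amplicon
sequencing, the raw data are millions of short reads per target site and
the questions are always the same: what fraction of reads carry an indel at
the cut site, the intended base edit, exactly the programmed prime edit, or
an integrated GUIDE-seq dsODN tag — and, in vitro, how fast does the enzyme
cut and how much of the nominal protein is actually active? `crisprquant`
implements this quantification layer as a tested, reusable package for
people benchmarking engineered nuclease and editor variants.

## What it computes

**Read-level pipeline.** Reads are aligned to their reference amplicon with
a fitting (semiglobal) affine-gap aligner (match +1, mismatch −4, gap open
−6, gap extend −1; indels left-aligned), filtered on ≥75% identity over the
first 20 reference bases (threshold 15/20), and classified. With cut site
*c* (the blunt cut 3 bp 5' of the NGG PAM, between protospacer positions 17
and 18):

- **indel**: an insertion/deletion whose left-aligned start lies in
  *c* ± 2 bp; frequency = indel reads / total reads;
- **intended substitution** (base editing): all specified substitutions
  present and no indel anywhere in the read;
- **intended prime edit**: the read's indel content equals exactly the
  programmed insertion/deletion; any other indel counts toward the indel
  background;
- **dsODN tag**: exact occurrence of the GUIDE-seq tag center 15-mer
  `GTTGTCATATGTTAA` / `TTAACATATGACAAC` in either orientation.

**Derived metrics.** Per-position base-editing profiles with editing-window
(protospacer 4–8) vs bystander partition, off-target/on-target activity
ratios, per-pair activity normalisation, Hamming mismatch filtering for
candidate off-target sites (retain ≤7 mismatches), GUIDE-seq on-target
specificity (% on-target reads of all reads), median/IQR summaries, and the
standard reporting filters (>70% on-target, <5% low-editing flag).

**Kinetics.** One-phase exponential decay fits
`cleaved(t) = P·(1 − e^(−t/τ))` give the cleavage rate constant `k = 1/τ`
from time courses sampled on fast (3–30 s), medium (3–300 s) or slow
(3–3600 s) grids; single-turnover titration fits `intact(r) = e^(−a·r)`
estimate the active enzyme fraction `a` from nominal enzyme:plasmid ratio
series.

**Synthetic data.** A seeded simulator generates amplicon reads with known
per-read truth (indel/base-edit/prime-edit/tag mixtures, per-base error)
and noisy kinetics observations, so every stage of the pipeline is
validated against ground truth without any external data.

## Worked example

```r
library(crisprquant)

ref <- amplicon_reference(
  "demo_site",
  "ATGCCGCTCACTGATCAGCTACGTCTGGCATCGTACGATCGTTAGCATGCACGTTCAGATCGGATACGTC",
  protospacer_start = 5, strand = "+", pam = "NGG")
ref
#> <amplicon_ref> demo_site: 70 bp, protospacer GCTCACTGATCAGCTACGTC (+ strand), PAM TGG, cut site 22

sim <- simulate_edited_reads(read_sim_config(
  ref, n_reads = 1000, indel_freq = 0.25, tag_freq = 0.05,
  sub_edits = data.frame(position = 5, from = "A", to = "G", frequency = 0.2),
  seq_error_rate = 0.001, seed = 42))

spec <- edit_spec(ref, substitutions = data.frame(position = 5, from = "A",
                                                  to = "G"))
q <- quantify_sample(sim, ref, spec = spec, mode = "all")
q$outcome[c("n_indel", "n_intended_sub", "n_tag",
            "indel_freq", "sub_freq", "tag_freq")]
#>   n_indel n_intended_sub n_tag indel_freq sub_freq tag_freq
#> 1     269            117    42      0.269    0.117    0.042
```

269/1000 reads carry a cut-site indel (configured rate 0.25), 42 carry the
dsODN tag (configured 0.05). The intended A5→G substitution is applied only
to reads not already assigned an indel/tag class, so its expected read
fraction is (1 − 0.25 − 0.05) × 0.2 = 0.14; the observed 0.117 is within
sampling noise. The per-position profile expresses editing among non-indel
reads, where A5 editing is accordingly higher:

```r
prof <- base_edit_profile(q, target_base = "A")
prof[prof$is_target, c("position", "edited_fraction", "in_window")]
#>    position edited_fraction in_window
#> 5         5     0.169811321      TRUE
#> 9         9     0.000000000     FALSE
#> 12       12     0.001451379     FALSE
#> 16       16     0.001451379     FALSE
```

Position 5 sits inside the editing window; the trace of editing at 12/16 is
sequencing error (rate 0.001). Kinetics, on simulated observations:

```r
tc <- simulate_timecourse(kin_sim_config(tau = 50,
                                         times = sampling_grid("medium"),
                                         noise_sd = 0.02, seed = 1))
fit_one_phase_decay(tc)
#> <kinetics_fit> k = 0.02018 1/s (tau = 49.56 s), plateau = 1.001, SSE = 0.00183

ti <- simulate_titration(kin_sim_config(active_fraction = 0.6,
                                        noise_sd = 0.02, seed = 1))
estimate_active_fraction(ti, nominal_conc = 31)
#> <titration_fit> active fraction = 0.602 (raw 0.602), SSE = 0.00151
```

The true rate constant is 1/50 = 0.02 s⁻¹ and the true active fraction 0.6;
both are recovered within the 2% observation noise.

An end-to-end run (simulate → align → call → tables, with a JSON manifest)
is one call:

```r
run_pipeline(demo_run_config(out_dir = "demo_out"))
```

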