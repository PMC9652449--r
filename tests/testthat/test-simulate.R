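test_that("edit-free configurations reproduce the reference prefix", {
  ref <- demo_amplicon()
  sim <- simulate_edited_reads(read_sim_config(ref, 50, seed = 1))
  expect_true(all(sim$sequence == substr(ref$sequence, 1, 50)))
  expect_true(all(sim$truth$class == "unedited"))
})

test_that("degenerate categorical puts every read in the indel class", {
  ref <- demo_amplicon()
  sim <- simulate_edited_reads(read_sim_config(ref, 100, indel_freq = 1,
                                               seed = 2))
  expect_equal(sum(sim$truth$class == "indel"), 100L)
  expect_true(all(!is.na(sim$truth$indel_len)))
  # every simulated indel start is canonical and inside the +/-2 bp window
  expect_true(all(abs(sim$truth$indel_start - ref$cut_site) <= 2))
})

test_that("empirical class fractions concentrate around the configured rates", {
  ref <- demo_amplicon()
  sim <- simulate_edited_reads(read_sim_config(ref, 2000, indel_freq = 0.10,
                                               seed = 3))
  se3 <- 3 * sqrt(0.1 * 0.9 / 2000)
  expect_lt(abs(mean(sim$truth$class == "indel") - 0.10), se3)

  # joint configuration: every class marginal within 3 binomial SE
  pe <- list(type = "insertion", position = ref$cut_site, sequence = "T",
             frequency = 0.15)
  cfg <- read_sim_config(ref, 3000, indel_freq = 0.2, prime_edit = pe,
                         background_indel_freq = 0.05, tag_freq = 0.1,
                         sub_edits = data.frame(position = 5, from = "A",
                                                to = "G", frequency = 0.5),
                         seed = 4)
  sim <- simulate_edited_reads(cfg)
  truth_freqs <- c(indel = 0.2, intended_pe = 0.15, background_indel = 0.05,
                   tag = 0.1)
  for (cl in names(truth_freqs)) {
    p <- truth_freqs[[cl]]
    expect_lt(abs(mean(sim$truth$class == cl) - p),
              3 * sqrt(p * (1 - p) / 3000), label = cl)
  }
  # substitution overlay applies to the class-free remainder at rate 0.5
  p_sub <- (1 - sum(truth_freqs)) * 0.5
  expect_lt(abs(mean(sim$truth$class == "intended_sub") - p_sub),
            3 * sqrt(p_sub * (1 - p_sub) / 3000))
})

test_that("identical config and seed give byte-identical FASTQ and truth", {
  ref <- demo_amplicon()
  cfg <- read_sim_config(ref, 300, indel_freq = 0.3, tag_freq = 0.1,
                         seq_error_rate = 0.01, seed = 99)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  s1 <- simulate_edited_reads(cfg); write_fastq(s1, f1)
  s2 <- simulate_edited_reads(cfg); write_fastq(s2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(s1$truth, s2$truth)
})

test_that("simulator rejects invalid configurations", {
  ref <- demo_amplicon()
  expect_error(read_sim_config(ref, 100, read_len = 20), ">= 25")
  expect_error(read_sim_config(ref, 100, indel_freq = 0.7, tag_freq = 0.5),
               "sum to at most 1")
  expect_error(read_sim_config(ref, 100,
                               sub_edits = data.frame(position = 1,
                                                      from = "A", to = "G",
                                                      frequency = 0.1)),
               "source base mismatch")  # position 1 is G on this protospacer
  expect_error(read_sim_config(ref, 100,
                               prime_edit = list(type = "insertion",
                                                 position = 22,
                                                 sequence = "C",
                                                 frequency = 0.1)),
               "canonical")  # inserting C right after a reference C
})

test_that("tag reads carry the dsODN center 15-mer in either orientation", {
  ref <- demo_amplicon()
  sim <- simulate_edited_reads(read_sim_config(ref, 400, tag_freq = 1,
                                               seed = 5))
  expect_true(all(detect_dsodn_tag(sim$sequence)))
  expect_setequal(unique(sim$truth$tag_orientation), c("+", "-"))
})

test_that("noiseless time courses equal the closed form", {
  cfg <- kin_sim_config(tau = 30, plateau = 1, times = c(3, 10, 30, 100),
                        noise_sd = 0, seed = 1)
  tc <- simulate_timecourse(cfg)
  expect_equal(tc$cleaved[3], 1 - exp(-1), tolerance = 1e-9)
  expect_equal(tc$cleaved, 1 - exp(-tc$time / 30), tolerance = 1e-9)
  # t -> 0 limit: the curve starts at zero
  expect_equal(1 * (1 - exp(-0 / 30)), 0)

  noisy <- simulate_timecourse(kin_sim_config(tau = 300,
                                              times = sampling_grid("slow"),
                                              noise_sd = 0.02, seed = 8))
  expect_true(all(abs(noisy$cleaved - (1 - exp(-noisy$time / 300))) <=
                    5 * 0.02))
  expect_true(all(noisy$cleaved >= 0 & noisy$cleaved <= 1))
})

test_that("noiseless titrations equal the single-turnover model", {
  cfg <- kin_sim_config(active_fraction = 1, ratios = c(0.8, 1, 2, 4, 8, 12),
                        seed = 1)
  ti <- simulate_titration(cfg)
  expect_equal(ti$intact[ti$ratio == 1], exp(-1), tolerance = 1e-9)
  expect_equal(ti$intact, exp(-ti$ratio), tolerance = 1e-9)

  ti0 <- simulate_titration(kin_sim_config(active_fraction = 0, seed = 1))
  expect_true(all(ti0$intact == 1))

  ti5 <- simulate_titration(kin_sim_config(active_fraction = 0.5, seed = 1))
  expect_true(all(diff(ti5$intact) <= 0))  # monotone non-increasing

  expect_error(kin_sim_config(times = c(3, 2, 10)), "strictly increasing")
  expect_error(kin_sim_config(ratios = c(1, 25)), "\\(0, 20\\]")
})

test_that("GUIDE-seq read-set assembly validates and annotates sites", {
  target <- "GCTCACTGATCAGCTACGTC"
  sites <- data.frame(
    sequence = c(target, "GCTCACTGATCAGCTACGAA", "ACTCACTGATCAGCTACGAA"),
    reads = c(900L, 80L, 20L),
    on_target = c(TRUE, FALSE, FALSE))
  rs <- simulate_guideseq_readset(target, sites)
  expect_equal(attr(rs, "total_reads"), 1000L)
  expect_equal(rs$mismatches, c(0L, 2L, 3L))

  set.seed(21)
  rnd <- data.frame(sequence = replicate(5, random_dna(20)),
                    reads = sample(1:500, 5), on_target = c(TRUE, rep(FALSE, 4)))
  rs2 <- simulate_guideseq_readset(rnd$sequence[1], rnd)
  expect_equal(attr(rs2, "total_reads"), sum(rnd$reads))

  expect_error(simulate_guideseq_readset(target,
                                         transform(sites, on_target = FALSE)),
               "exactly one site")
  expect_error(simulate_guideseq_readset(target,
                                         transform(sites, reads = 0L)),
               "positive")
})

test_that("class assignment is monotone in the configured indel frequency", {
  ref <- demo_amplicon()
  prev <- -1L
  for (f in c(0.05, 0.2, 0.5, 0.8)) {
    sim <- simulate_edited_reads(read_sim_config(ref, 500, indel_freq = f,
                                                 seed = 77))
    n <- sum(sim$truth$class == "indel")
    expect_gte(n, prev)
    prev <- n
  }
})
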