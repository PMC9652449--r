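test_that("indel calls respect the +/-2 bp window around the cut exactly", {
  ref <- demo_amplicon()
  cut <- ref$cut_site

  # deletions: left-aligned start at every window offset is called
  for (off in -2:2) {
    a <- align_semiglobal(read_with_deletion(ref, cut + off, 1), ref)
    expect_false(is.null(call_indel(a, ref)), label = paste("del offset", off))
  }
  # one step outside on either side is not
  for (off in c(-3, 3)) {
    a <- align_semiglobal(read_with_deletion(ref, cut + off, 1), ref)
    expect_null(call_indel(a, ref), label = paste("del offset", off))
  }

  # insertions at the inter-base boundary offsets (sequences chosen not to
  # shift under left-alignment)
  a <- align_semiglobal(read_with_insertion(ref, cut - 2, "CCG"), ref)
  expect_equal(call_indel(a, ref)$type, "insertion")
  a <- align_semiglobal(read_with_insertion(ref, cut - 3, "CCG"), ref)
  expect_null(call_indel(a, ref))

  # substitution-only read: no indel op, no call
  a <- align_semiglobal(read_with_subs(ref, 5, "G"), ref)
  expect_null(call_indel(a, ref))

  # a 1-bp deletion starting exactly at the cut
  a <- align_semiglobal(read_with_deletion(ref, cut, 1), ref)
  d <- call_indel(a, ref)
  expect_equal(d$type, "deletion")
  expect_equal(d$ref_start, cut)
})

test_that("strict indel mode vetoes reads with distal mismatches", {
  ref <- demo_amplicon()
  r <- read_with_deletion(ref, ref$cut_site, 2)
  substr(r, 40, 40) <- chartr("ACGT", "CATG", substr(r, 40, 40))
  a <- align_semiglobal(r, ref)
  expect_false(is.null(call_indel(a, ref)))                      # default
  expect_null(call_indel(a, ref, strict_read = TRUE))            # strict
})

test_that("base-edit calls require the intended substitution and no indels", {
  ref <- demo_amplicon()
  spec <- edit_spec(ref, substitutions = data.frame(position = 5, from = "A",
                                                    to = "G"))
  a <- align_semiglobal(read_with_subs(ref, 5, "G"), ref)
  cb <- call_base_edit(a, ref, spec)
  expect_true(cb$intended)
  expect_equal(cb$positions[5], "G")
  expect_equal(cb$positions[-5], strsplit(ref$protospacer, "")[[1]][-5])

  # the intended substitution plus a 1-bp insertion at the cut: vetoed
  r <- read_with_insertion(ref, ref$cut_site,
                           "A")  # A after reference C: canonical
  substr(r, protospacer_ref_index(ref, 5) + 1,
         protospacer_ref_index(ref, 5) + 1) <- "G"
  cb2 <- call_base_edit(align_semiglobal(r, ref), ref, spec)
  expect_false(cb2$intended)

  # unedited read
  cb3 <- call_base_edit(align_semiglobal(substr(ref$sequence, 1, 50), ref),
                        ref, spec)
  expect_false(cb3$intended)
  expect_equal(paste(cb3$positions, collapse = ""), ref$protospacer)
})

test_that("base-edit positions are reported on the non-targeted strand", {
  rc <- demo_amplicon_minus()
  spec <- edit_spec(rc, substitutions = data.frame(position = 5, from = "A",
                                                   to = "G"))
  r <- read_with_subs(rc, 5, "G", read_len = nchar(rc$sequence))
  cb <- call_base_edit(align_semiglobal(r, rc), rc, spec)
  expect_true(cb$intended)
  expect_equal(cb$positions[5], "G")
})

test_that("prime-edit calls discriminate the aimed edit from background", {
  ref <- demo_amplicon()
  spec <- edit_spec(ref, intended_indel = list(type = "insertion",
                                               position = ref$cut_site,
                                               sequence = "T"))
  exact <- align_semiglobal(read_with_insertion(ref, ref$cut_site, "T"), ref)
  expect_equal(call_prime_edit(exact, ref, spec), "intended_pe")

  other <- align_semiglobal(read_with_deletion(ref, ref$cut_site, 2), ref)
  expect_equal(call_prime_edit(other, ref, spec), "background_indel")

  # intended edit plus an extra distal deletion is not "only the intended"
  r <- read_with_insertion(ref, ref$cut_site, "T", read_len = 50)
  r <- paste0(substr(r, 1, 39), substr(r, 41, 50))  # delete read base 40
  both <- align_semiglobal(r, ref)
  expect_equal(call_prime_edit(both, ref, spec), "background_indel")

  clean <- align_semiglobal(substr(ref$sequence, 1, 50), ref)
  expect_equal(call_prime_edit(clean, ref, spec), "none")

  nospec <- edit_spec(ref)
  expect_error(call_prime_edit(exact, ref, nospec), "intended indel")
})

test_that("dsODN tag detection is exact-substring in either orientation", {
  ref <- demo_amplicon()
  fwd <- read_with_insertion(ref, ref$cut_site, "GTTGTCATATGTTAA")
  rev <- read_with_insertion(ref, ref$cut_site, "TTAACATATGACAAC")
  expect_true(detect_dsodn_tag(fwd))
  expect_true(detect_dsodn_tag(rev))
  expect_true(detect_dsodn_tag(tolower(fwd)))
  expect_false(detect_dsodn_tag(substr(ref$sequence, 1, 50)))

  # any single internal substitution breaks detection
  for (p in 1:15) {
    decoy <- "GTTGTCATATGTTAA"
    substr(decoy, p, p) <- chartr("ACGT", "CATG", substr(decoy, p, p))
    expect_false(detect_dsodn_tag(
      read_with_insertion(ref, ref$cut_site, decoy)), label = paste("pos", p))
  }
})

test_that("sample quantification computes exact count ratios", {
  ref <- demo_amplicon()
  reads <- c(rep(substr(ref$sequence, 1, 50), 180),
             rep(read_with_deletion(ref, ref$cut_site, 2), 20))
  q <- quantify_sample(reads, ref, mode = "nuclease")
  expect_equal(q$outcome$total_reads, 200L)
  expect_equal(q$outcome$n_indel, 20L)
  expect_equal(q$outcome$indel_freq, 0.10)
  # counts partition the reads
  cnt <- q$outcome[c("n_discarded", "n_unedited", "n_indel", "n_intended_sub",
                     "n_intended_pe", "n_background_indel", "n_tag")]
  expect_equal(sum(unlist(cnt)), q$outcome$total_reads)
  # frequencies recompute exactly from counts
  expect_equal(q$outcome$indel_freq,
               q$outcome$n_indel / q$outcome$denominator)
})

test_that("samples with no passing reads warn and report zero frequencies", {
  ref <- demo_amplicon()
  reads <- rep(substr(ref$sequence, 26, 70), 10)  # all miss the 20-bp prefix
  expect_warning(q <- quantify_sample(reads, ref, mode = "nuclease"),
                 "prefix-identity")
  expect_equal(q$outcome$n_discarded, 10L)
  expect_equal(q$outcome$indel_freq, 0)
  expect_true(q$outcome$no_passing_reads)
})

test_that("discarded reads can be kept in or out of the denominator", {
  ref <- demo_amplicon()
  reads <- c(rep(substr(ref$sequence, 1, 50), 60),
             rep(read_with_deletion(ref, ref$cut_site, 1), 20),
             rep(substr(ref$sequence, 26, 70), 20))   # discarded
  q1 <- quantify_sample(reads, ref, mode = "nuclease")
  expect_equal(q1$outcome$indel_freq, 20 / 80)
  q2 <- quantify_sample(reads, ref, mode = "nuclease",
                        count_discarded = TRUE)
  expect_equal(q2$outcome$indel_freq, 20 / 100)
})

test_that("per-read calls match the simulator truth on error-free reads", {
  ref <- demo_amplicon()
  pe <- list(type = "insertion", position = ref$cut_site, sequence = "T",
             frequency = 0.15)
  cfg <- read_sim_config(ref, 800, indel_freq = 0.3, prime_edit = pe,
                         tag_freq = 0.1,
                         sub_edits = data.frame(position = 5, from = "A",
                                                to = "G", frequency = 0.5),
                         seed = 31)
  sim <- simulate_edited_reads(cfg)
  spec <- edit_spec(ref,
                    substitutions = data.frame(position = 5, from = "A",
                                               to = "G"),
                    intended_indel = pe[c("type", "position", "sequence")])
  q <- quantify_sample(sim, ref, spec = spec, mode = "all")
  expect_identical(q$calls$class, sim$truth$class)
})

test_that("called indel counts are monotone in the simulated indel rate", {
  ref <- demo_amplicon()
  prev <- -1L
  for (f in c(0.1, 0.3, 0.6)) {
    sim <- simulate_edited_reads(read_sim_config(ref, 400, indel_freq = f,
                                                 seed = 13))
    q <- quantify_sample(sim, ref, mode = "nuclease")
    expect_gte(q$outcome$n_indel, prev)
    prev <- q$outcome$n_indel
  }
})

test_that("allele tables aggregate identical sequences with their class", {
  ref <- demo_amplicon()
  reads <- c(rep(substr(ref$sequence, 1, 50), 3),
             rep(read_with_deletion(ref, ref$cut_site, 1), 2))
  q <- quantify_sample(reads, ref, mode = "nuclease")
  expect_equal(nrow(q$alleles), 2L)
  expect_equal(q$alleles$count, c(3L, 2L))
  expect_setequal(q$alleles$class, c("unedited", "indel"))
})
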