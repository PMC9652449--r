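# Shared fixtures, built in code. The demo amplicon is 70 bp with the
# protospacer at reference index 5 (+ strand, TGG PAM), so the blunt cut site
# sits at inter-base coordinate 22; it contains adenines at protospacer
# positions 5 (editing window) and 9/12/16 (bystanders), no homopolymer
# longer than 2 near the cut, and no dsODN 15-mer.
DEMO_SEQ <- "ATGCCGCTCACTGATCAGCTACGTCTGGCATCGTACGATCGTTAGCATGCACGTTCAGATCGGATACGTC"

demo_amplicon <- function() {
  amplicon_reference("demo_site", DEMO_SEQ, 5L, "+", "NGG")
}

# the same locus presented on the opposite strand of the amplicon
demo_amplicon_minus <- function() {
  amplicon_reference("demo_site_rc", revcomp(DEMO_SEQ),
                     nchar(DEMO_SEQ) - 1L - 5L, "-", "NGG")
}

# read = amplicon 5' prefix with a deletion of `len` starting at 0-based
# reference index `at`
read_with_deletion <- function(ref, at, len, read_len = 50L) {
  s <- ref$sequence
  substr(paste0(substr(s, 1L, at), substr(s, at + len + 1L, nchar(s))),
         1L, read_len)
}

# read with `seq` inserted at 0-based inter-base point `at`
read_with_insertion <- function(ref, at, seq, read_len = 50L) {
  s <- ref$sequence
  substr(paste0(substr(s, 1L, at), seq, substr(s, at + 1L, nchar(s))),
         1L, read_len)
}

# read with substitutions at protospacer positions (non-targeted strand)
read_with_subs <- function(ref, positions, to, read_len = 50L) {
  s <- substr(ref$sequence, 1L, read_len)
  idx <- protospacer_ref_index(ref, positions) + 1L
  if (ref$strand == "-") to <- chartr("ACGTN", "TGCAN", to)
  for (i in seq_along(idx)) substr(s, idx[i], idx[i]) <- to[i]
  s
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random read/reference pairs exercising the aligner: related pairs carry a
# random indel plus scattered mismatches, unrelated pairs are independent
random_alignment_case <- function() {
  m <- sample(10:40, 1)
  ref <- random_dna(m)
  if (runif(1) < 0.25) {
    n <- sample(5:30, 1)
    return(list(read = random_dna(n), ref = ref))
  }
  start <- sample(0:max(0, m - 10), 1)
  len <- sample(5:min(30, m - start), 1)
  read <- substr(ref, start + 1, start + len)
  if (runif(1) < 0.6 && nchar(read) > 6) { # indel
    at <- sample(2:(nchar(read) - 2), 1)
    k <- sample(1:4, 1)
    if (runif(1) < 0.5) {
      read <- paste0(substr(read, 1, at),
                     substr(read, min(at + k + 1, nchar(read) + 1),
                            nchar(read)))
    } else {
      read <- paste0(substr(read, 1, at), random_dna(k),
                     substr(read, at + 1, nchar(read)))
    }
  }
  nmm <- sample(0:2, 1)
  if (nmm > 0 && nchar(read) > 2) {
    for (p in sample(nchar(read), min(nmm, nchar(read)))) {
      substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(read, p, p)), 1)
    }
  }
  if (nchar(read) < 5) read <- paste0(read, random_dna(5))
  list(read = read, ref = ref)
}
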