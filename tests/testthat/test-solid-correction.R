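test_that("k-mer quality is the product of per-position correctness", {
  reads <- reads_from_seqs("ACG", phred = 10L)       # q = 0.1 everywhere
  idx <- collect_statistics(reads, 3)
  expect_equal(kmer_quality(idx), 0.729, tolerance = 1e-9)

  hi <- collect_statistics(reads_from_seqs("ACG", phred = 40L), 3)
  expect_gt(kmer_quality(hi), 0.999)

  lo <- collect_statistics(read_table("r", "ACG", "!II"), 3)  # one q ~ 1
  expect_lt(kmer_quality(lo), 1e-9)
})

test_that("cluster quality is one minus the product of member failure odds", {
  expect_equal(cluster_quality(0.9), 0.9)            # singleton not special-cased
  expect_equal(cluster_quality(c(0.5, 0.5)), 0.75)
  p <- c(0.3, 0.2, 0.6)
  expect_gte(cluster_quality(c(p, 0.01)), cluster_quality(p))  # monotone
  expect_error(cluster_quality(numeric(0)), "empty")
})

test_that("solid selection thresholds cluster quality and indexes centers", {
  reads <- reads_from_seqs(c(rep("ACGTG", 3), "ACATG"), phred = 30L)
  idx <- collect_statistics(reads, 5)
  mem <- hamming_components(idx)
  sc <- subcluster_components(idx, mem)
  p_x <- kmer_quality(idx)

  ss <- select_solid(sc, idx, threshold = 0.5)
  expect_true(all(ss$clusters$p_C[ss$clusters$solid_center] > 0.5))
  expect_equal(length(ss$center_of), length(ss$kmers))
  expect_true(all(ss$center_of >= 1L & ss$center_of <= length(ss$kmers)))

  # threshold above every p_C: nothing solid; near zero: every center solid
  hi <- select_solid(sc, idx, threshold = 1 - 1e-15)
  expect_equal(sum(hi$solid), 0L)
  lo <- select_solid(sc, idx, threshold = 1e-12)
  expect_equal(sum(lo$solid), length(unique(lo$center_of)))
})

test_that("unobserved consensus centers get synthetic quality and can vote", {
  # three equidistant variants whose consensus is none of them
  reads <- reads_from_seqs(c("AACGT", "ACCTT", "CACTT"), phred = 35L)
  idx <- collect_statistics(reads, 5)
  mem <- hamming_components(idx, tau = 2)
  sc <- subcluster_components(idx, mem, hammer_emulate = TRUE)
  novel <- setdiff(sc$clusters$center, idx$kmers)
  if (length(novel) > 0L) {
    ss <- select_solid(sc, idx, threshold = 0.5)
    ext <- which(!ss$observed)
    expect_equal(ss$kmers[ext], novel)
    expect_true(all(ss$p_correct[ext] > 0 & ss$p_correct[ext] < 1))
  } else {
    succeed("consensus happened to be observed")
  }
})

test_that("expansion closes covered reads and chains across reads", {
  # read of length 7, k = 5: solid occurrences at offsets 0 and 2 cover
  # positions 0..6, so the offset-1 k-mer becomes solid
  reads <- reads_from_seqs("ACGTGTG", phred = 35L)
  idx <- collect_statistics(reads, 5)
  mem <- hamming_components(idx)
  sc <- subcluster_components(idx, mem)
  ss <- select_solid(sc, idx, threshold = 1 - 1e-15)   # start with nothing
  expect_equal(sum(ss$solid), 0L)
  ids <- setNames(seq_along(idx$kmers), idx$kmers)
  ss$solid[ids[c("ACGTG", "GTGTG")]] <- TRUE           # offsets 0 and 2
  out <- expand_solid(reads, ss, idx)
  expect_true(out$solid[ids["CGTGT"]])

  # a read with an uncovered position contributes nothing
  ss2 <- select_solid(sc, idx, threshold = 1 - 1e-15)
  ss2$solid[ids["ACGTG"]] <- TRUE                      # positions 5,6 uncovered
  out2 <- expand_solid(reads, ss2, idx)
  expect_equal(sum(out2$solid), 1L)

  # chain: closing read A makes read B fully covered on the next pass.
  # Seeds cover A (offsets 0, 2), so A's middle k-mer CGTGT turns solid;
  # B = CGTGTAA is covered only once CGTGT is solid (with seed TGTAA at
  # offset 2), which in turn closes B's middle k-mer GTGTA.
  chain <- reads_from_seqs(c("ACGTGTG", "CGTGTAA"), phred = 35L)
  cidx <- collect_statistics(chain, 5)
  cmem <- hamming_components(cidx)
  csc <- subcluster_components(cidx, cmem)
  css <- select_solid(csc, cidx, threshold = 1 - 1e-15)
  cids <- setNames(seq_along(cidx$kmers), cidx$kmers)
  css$solid[cids[c("ACGTG", "GTGTG", "TGTAA")]] <- TRUE
  cout <- expand_solid(chain, css, cidx)
  expect_true(all(cout$solid[cout$observed]))
  expect_true(cout$solid[cids["GTGTA"]])
})

test_that("expansion is monotone and independent of read order", {
  set.seed(47)
  for (trial in 1:10) {
    reads <- reads_from_seqs(random_read_seqs(12, 14), phred = 30L)
    idx <- collect_statistics(reads, 7)
    mem <- hamming_components(idx)
    sc <- subcluster_components(idx, mem)
    ss <- select_solid(sc, idx, threshold = 0.99)
    before <- ss$solid
    out <- expand_solid(reads, ss, idx)
    expect_true(all(out$solid[before]))          # monotone growth

    perm <- sample(nrow(reads))
    idx_p <- collect_statistics(reads[perm, ], 7)
    sc_p <- subcluster_components(idx_p, hamming_components(idx_p))
    ss_p <- select_solid(sc_p, idx_p, threshold = 0.99)
    out_p <- expand_solid(reads[perm, ], ss_p, idx_p)
    expect_identical(out$solid, out_p$solid)     # k-mer ids are order-free
  }
})

test_that("consensus voting corrects a single erroneous base", {
  # many clean copies of a region + one read with a single error; the
  # erroneous k-mers' solid centers vote the true base
  genome <- "ACGTGTGACCTGA"
  clean <- substring(genome, 1:7, 7:13)
  bad <- clean[4]
  substr(bad, 4, 4) <- "T"                       # one substitution
  reads <- reads_from_seqs(c(rep(clean, 4), bad), phred = 30L)
  idx <- collect_statistics(reads, 5)
  sc <- subcluster_components(idx, hamming_components(idx))
  ss <- expand_solid(reads, select_solid(sc, idx, 1 - 1e-3), idx)
  res <- correct_reads(reads, ss, idx)
  n <- nrow(reads)
  expect_equal(res$reads$seq[n], clean[4])
  expect_equal(res$outcome$n_changed[n], 1L)
  expect_false(any(res$outcome$changed[-n]))     # clean reads untouched
})

test_that("voting preserves length, zero-vote positions and short reads", {
  reads <- reads_from_seqs(c("ACGTGTG", "ACG"), phred = 35L)  # read 2 < k
  idx <- collect_statistics(reads, 5)
  sc <- subcluster_components(idx, hamming_components(idx))
  ss <- expand_solid(reads, select_solid(sc, idx, 1 - 1e-3), idx)
  res <- correct_reads(reads, ss, idx)
  expect_equal(nchar(res$reads$seq), nchar(reads$seq))
  expect_equal(res$reads$seq[2], "ACG")          # no k-mers, unchanged
  expect_identical(res$reads$raw_qual, reads$raw_qual)

  # a read whose only k-mers contain N gets no votes anywhere
  rn <- reads_from_seqs("ACNTGTG", phred = 35L)
  idxn <- collect_statistics(rn, 5)
  scn <- subcluster_components(idxn, hamming_components(idxn))
  ssn <- select_solid(scn, idxn, 1e-12)
  resn <- correct_reads(rn, ssn, idxn)
  expect_equal(resn$reads$seq, "ACNTGTG")
})

test_that("quality trimming drops only trailing low-quality bases", {
  reads <- read_table("r", "ACGTACGT", "IIIII!!!")
  out <- trim_reads(reads, min_phred = 20)
  expect_equal(out$seq, "ACGTA")
  expect_equal(out$raw_qual, "IIIII")
  expect_equal(lengths(out$qual), 5L)
  # interior bad base is kept (only the tail is trimmed)
  reads2 <- read_table("r", "ACGTACGT", "II!IIIII")
  expect_equal(trim_reads(reads2, 20)$seq, "ACGTACGT")
})
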