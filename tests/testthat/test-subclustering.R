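test_that("fixed-rate likelihood matches its closed form", {
  expect_equal(hammer_likelihood("ACGTG", "ACGTG", 0.01), 5 * log(0.99),
               tolerance = 1e-12)
  expect_equal(hammer_likelihood("ACGTG", "ACATG", 0.01),
               log(0.99^4 * 0.01), tolerance = 1e-12)
  expect_lt(hammer_likelihood("ACGTG", "ACATG", 1e-12), -20)
  expect_error(hammer_likelihood("ACG", "AC"), "length mismatch")
})

test_that("quality-weighted likelihood multiplies q over mismatches, 1-q over matches", {
  expect_equal(kmer_log_likelihood("ACG", "ACG", rep(0.1, 3)), log(0.729),
               tolerance = 1e-12)
  expect_equal(kmer_log_likelihood("ACG", "AGG", c(0.1, 0.2, 0.1)),
               log(0.2 * 0.9 * 0.9), tolerance = 1e-12)
  expect_equal(kmer_log_likelihood("ACG", "ACG", rep(1e-10, 3)), 0,
               tolerance = 1e-9)
  expect_error(kmer_log_likelihood("ACG", "AC", c(0.1, 0.1)), "length mismatch")
})

test_that("consensus center is the weighted position-wise majority", {
  expect_equal(consensus_center("ACGTG"), "ACGTG")
  expect_equal(consensus_center(c("ACGTG", "ACATG", "ATGTG")), "ACGTG")
  expect_equal(consensus_center(c("ACGTG", "ACATG"), weight = c(1, 3)), "ACATG")
  # alphabet-order tie-break: A and C tied at position 1
  expect_equal(consensus_center(c("AT", "CT")), "AT")
  expect_error(consensus_center(character(0)), "empty")
})

test_that("BIC objective reproduces hand-computed values", {
  # one member, count 1, uniform q = 0.1, k = 3: penalty vanishes (log 1 = 0)
  reads <- reads_from_seqs("ACG", phred = 10L)
  idx <- collect_statistics(reads, 3)
  prof <- error_profile(idx)
  expect_equal(bic_objective(1L, 1L, "ACG", idx, prof), 2 * log(0.729),
               tolerance = 1e-9)

  # two members: ratio of objectives isolates the 3km + m - 1 penalty at log N
  reads2 <- reads_from_seqs(c("ACG", "ACG", "ACT"), phred = 10L)
  idx2 <- collect_statistics(reads2, 3)
  prof2 <- error_profile(idx2)
  members <- 1:2
  obj1 <- bic_objective(members, c(1L, 1L), "ACG", idx2, prof2)
  # m = 1 penalty equals 3k log N with N = total multiset size (2 + 1 = 3)
  w <- idx2$count[members]
  loglik <- w[1] * kmer_log_likelihood("ACG", "ACG", prof2[1, ]) +
    w[2] * kmer_log_likelihood("ACT", "ACG", prof2[2, ])
  expect_equal(obj1, 2 * loglik - (3 * 3 * 1 + 0) * log(3), tolerance = 1e-9)
  # distinct-observation mode uses N = 2
  expect_equal(bic_objective(members, c(1L, 1L), "ACG", idx2, prof2,
                             distinct = TRUE),
               2 * loglik - 9 * log(2), tolerance = 1e-9)
})

test_that("duplicating a cluster without reassigning strictly lowers the objective", {
  set.seed(29)
  reads <- reads_from_seqs(noisy_copies("ACGTACGTA", 20, phred = 30L),
                           phred = 30L)
  idx <- collect_statistics(reads, 9)
  prof <- error_profile(idx)
  members <- seq_along(idx$kmers)
  cen <- consensus_center(idx$kmers, idx$count)
  one <- bic_objective(members, rep(1L, length(members)), cen, idx, prof)
  dup <- bic_objective(members, rep(1L, length(members)), c(cen, cen), idx, prof)
  expect_lt(dup, one)
})

test_that("likelihood term is invariant under member reordering", {
  set.seed(31)
  reads <- reads_from_seqs(random_read_seqs(10, 9), phred = 20L)
  idx <- collect_statistics(reads, 9)
  prof <- error_profile(idx)
  members <- seq_along(idx$kmers)
  cen <- consensus_center(idx$kmers, idx$count)
  perm <- sample(members)
  expect_equal(
    bic_objective(members, rep(1L, length(members)), cen, idx, prof),
    bic_objective(perm, rep(1L, length(perm)), cen, idx, prof),
    tolerance = 1e-12)
})

test_that("m-means recovers two well-separated mass centers", {
  reads <- reads_from_seqs(c(rep("AAAAA", 20), rep("TTTTT", 20)))
  idx <- collect_statistics(reads, 5)
  prof <- error_profile(idx)
  res <- m_means(seq_along(idx$kmers), 2L, idx, prof)
  expect_setequal(res$centers, c("AAAAA", "TTTTT"))
  expect_equal(length(unique(res$assign)), 2L)
  # m = 1 degenerates to the consensus
  res1 <- m_means(seq_along(idx$kmers), 1L, idx, prof)
  expect_equal(res1$centers, consensus_center(idx$kmers, idx$count))
  expect_error(m_means(seq_along(idx$kmers), 5L, idx, prof), "out of range")
})

test_that("model selection recovers the true number of centers", {
  set.seed(37)
  c1 <- "ACGTACGTACGTACG"
  c2 <- "ACGAACGCACGGACG"  # distance 3 from c1
  expect_equal(hamming_distance(c1, c2), 3L)

  # two true centers, >= 20 occurrences each, Phred-30 noise
  reads2 <- reads_from_seqs(c(noisy_copies(c1, 25), noisy_copies(c2, 25)),
                            phred = 30L)
  idx2 <- collect_statistics(reads2, 15)
  res2 <- subcluster_component(seq_along(idx2$kmers), idx2, error_profile(idx2))
  expect_equal(res2$m, 2L)
  expect_setequal(res2$centers, c(c1, c2))

  # a single true center stays one cluster
  reads1 <- reads_from_seqs(noisy_copies(c1, 25), phred = 30L)
  idx1 <- collect_statistics(reads1, 15)
  res1 <- subcluster_component(seq_along(idx1$kmers), idx1, error_profile(idx1))
  expect_equal(res1$m, 1L)
  expect_equal(res1$centers, c1)

  # singleton component returns immediately
  idxs <- collect_statistics(reads_from_seqs("ACGTACGTACGTACG"), 15)
  ress <- subcluster_component(1L, idxs, error_profile(idxs))
  expect_equal(ress$m, 1L)
  expect_equal(ress$centers, c1)
})

test_that("greedy subclustering is bounded by the exhaustive partition oracle", {
  set.seed(41)
  for (trial in 1:5) {
    seqs <- c(noisy_copies("ACGTACGTA", sample(3:4, 1), phred = 25L),
              noisy_copies("ACGTTCGAA", sample(2:3, 1), phred = 25L))
    idx <- collect_statistics(reads_from_seqs(seqs, phred = 25L), 9)
    prof <- error_profile(idx)
    members <- seq_along(idx$kmers)
    if (length(members) > 6L || length(members) < 2L) next
    got <- subcluster_component(members, idx, prof)
    # replicate the m-sweep with exhaustive best-partition m-means
    best_prev <- oracle_best_objective(members, 1L, idx, prof)
    m <- 1L
    while (m < length(members)) {
      m <- m + 1L
      cand <- oracle_best_objective(members, m, idx, prof)
      if (cand$objective <= best_prev$objective) break
      best_prev <- cand
    }
    expect_lte(got$objective, best_prev$objective + 1e-6)
  }
})

test_that("well-separated heavy centers: greedy equals the exhaustive oracle", {
  reads <- reads_from_seqs(c(rep("AAAAAAAAA", 3), rep("TTTTTTTTT", 3)),
                           phred = 30L)
  idx <- collect_statistics(reads, 9)
  prof <- error_profile(idx)
  members <- seq_along(idx$kmers)
  got <- subcluster_component(members, idx, prof)
  oracle <- oracle_best_objective(members, got$m, idx, prof)
  expect_equal(got$objective, oracle$objective, tolerance = 1e-9)
  expect_setequal(got$centers, oracle$centers)
})

test_that("subclustering a whole index partitions every component", {
  set.seed(43)
  reads <- reads_from_seqs(random_read_seqs(20, 20, n_frac = 0.02),
                           phred = 25L)
  idx <- collect_statistics(reads, 9)
  mem <- hamming_components(idx)
  sc <- subcluster_components(idx, mem)
  expect_equal(sort(sc$assignments$kmer_id), seq_along(idx$kmers))
  # every cluster lies inside one component
  j <- dplyr::left_join(sc$assignments,
                        dplyr::distinct(sc$assignments[c("cluster", "component")]),
                        by = "cluster", suffix = c("", ".cl"))
  expect_true(all(j$component == j$component.cl))
  # emulation mode: exactly one cluster per component, consensus centers
  sch <- subcluster_components(idx, mem, hammer_emulate = TRUE)
  expect_equal(nrow(sch$clusters), max(mem))
  expect_true(all(sch$components$m == 1L))
})
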