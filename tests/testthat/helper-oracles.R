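# Independent oracles used across tests. These deliberately share no code
# with the package implementation beyond base R.

# Brute-force connected components of the distance-<=tau graph: full
# all-pairs Hamming distance matrix, then repeated label propagation.
brute_components <- function(kmers, tau) {
  n <- length(kmers)
  if (n == 0L) return(integer(0))
  chm <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  lab <- seq_len(n)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- colSums(t(chm) != chm[i, ])
    adj[i, ] <- d <= tau
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      m <- min(lab[adj[i, ]])
      if (m < lab[i]) {
        lab[lab == lab[i]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# Canonical form of a partition (for comparing memberships that may number
# components differently): sorted list of sorted member vectors.
partition_canon <- function(membership) {
  parts <- lapply(unname(split(seq_along(membership), membership)), sort)
  parts[order(vapply(parts, `[[`, integer(1), 1L))]
}

expect_same_partition <- function(a, b) {
  expect_identical(partition_canon(a), partition_canon(b))
}

random_kmers <- function(n, k) {
  unique(vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, character(1)))
}

# Uniform-quality read table from plain sequences.
reads_from_seqs <- function(seqs, phred = 40L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%d", seq_along(seqs))
  read_table(ids, seqs,
             vapply(nchar(seqs), function(l) strrep(intToUtf8(phred + 33L), l),
                    character(1)))
}

random_read_seqs <- function(n, len, n_frac = 0) {
  vapply(seq_len(n), function(i) {
    ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (n_frac > 0) {
      nn <- which(runif(len) < n_frac)
      ch[nn] <- "N"
    }
    paste(ch, collapse = "")
  }, character(1))
}

# All partitions of 1..n into exactly m non-empty blocks (restricted growth
# strings); n is tiny in tests.
set_partitions_m <- function(n, m) {
  out <- list()
  rec <- function(assign, next_block) {
    i <- length(assign) + 1L
    if (i > n) {
      if (next_block - 1L == m) out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (b in seq_len(min(next_block, m))) {
      rec(c(assign, b), max(next_block, b + 1L))
    }
  }
  rec(integer(0), 1L)
  out
}

# Best achievable BIC objective over every partition of the members into
# exactly m blocks (centers = weighted consensus of each block). Exhaustive
# counterpart of the greedy m-means inside subcluster_component().
oracle_best_objective <- function(members, m, index, profile,
                                  distinct = FALSE) {
  best <- -Inf
  best_part <- NULL
  for (assign in set_partitions_m(length(members), m)) {
    centers <- vapply(seq_len(m), function(b) {
      sel <- members[assign == b]
      consensus_center(index$kmers[sel], index$count[sel])
    }, character(1))
    obj <- bic_objective(members, assign, centers, index, profile, distinct)
    if (obj > best) {
      best <- obj
      best_part <- list(assign = assign, centers = centers)
    }
  }
  list(objective = best, assign = best_part$assign,
       centers = best_part$centers)
}

# Noisy copies of a center k-mer: per-base substitution with probability
# 10^(-phred/10), quality strings emitted at that Phred.
noisy_copies <- function(center, n, phred = 30L) {
  k <- nchar(center)
  p <- 10^(-phred / 10)
  vapply(seq_len(n), function(i) {
    ch <- strsplit(center, "", fixed = TRUE)[[1]]
    hit <- which(runif(k) < p)
    for (j in hit) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
    paste(ch, collapse = "")
  }, character(1))
}

# The three overlapping reads whose 5-mers form the worked clustering
# example used throughout the graph tests.
example_reads <- function(phred = 40L) {
  reads_from_seqs(c("ACGTGTG", "ACATGTG", "ACCTGTC"), phred = phred)
}

example_kmers <- c("ACGTG", "CGTGT", "GTGTG", "ACATG", "CATGT",
                   "ATGTG", "ACCTG", "CCTGT", "CTGTC")
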