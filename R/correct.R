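#' Correct reads by consensus voting of solid k-mers
#'
#' Step (6). For every valid k-mer occurrence in a read: a solid k-mer
#' votes its own letter at each read position it covers; a non-solid k-mer
#' whose subcluster center is solid votes the center's aligned letter.
#' After all votes, each position with at least one vote is replaced by the
#' majority letter (ties keep the original base when it is among the
#' leaders, otherwise resolve in A < C < G < T order); positions with no
#' votes keep the original base. Read length is always preserved, and
#' quality strings are left untouched.
#'
#' @param reads The read tibble.
#' @param solid A `solid_set` (after [expand_solid()], typically).
#' @param index The `kmer_index` for these reads.
#' @return List with `reads` (corrected tibble; `seq` updated, `qual` and
#'   `raw_qual` unchanged) and `outcome` (tibble `read`, `n_changed`,
#'   `changed`).
#' @export
correct_reads <- function(reads, solid, index) {
  k <- index$k
  n_ext <- length(solid$kmers)
  # per k-mer: the letters it votes with (its own if solid, its center's if
  # the center is solid, none otherwise), as a row of base codes
  vote_source <- rep(NA_integer_, n_ext)
  vote_source[solid$solid] <- which(solid$solid)
  not_solid <- which(!solid$solid)
  cent <- solid$center_of[not_solid]
  has_solid_center <- solid$solid[cent]
  vote_source[not_solid[has_solid_center]] <- cent[has_solid_center]
  voters <- which(!is.na(vote_source))
  vote_codes <- matrix(NA_integer_, n_ext, k)
  if (length(voters) > 0L) {
    vote_codes[voters, ] <-
      base_codes(kmer_char_matrix(solid$kmers[vote_source[voters]], k))
  }
  pos <- index$positions[!is.na(vote_source[index$positions$kmer_id]), ]
  pos_by_read <- split(pos[c("offset", "kmer_id")], pos$read)
  seqs <- reads$seq
  n_changed <- integer(nrow(reads))
  for (rname in names(pos_by_read)) {
    r <- as.integer(rname)
    p <- pos_by_read[[rname]]
    L <- nchar(seqs[r])
    votes <- matrix(0L, L, 4L)
    for (i in seq_len(nrow(p))) {
      rows <- (p$offset[i] + 1L):(p$offset[i] + k)
      idx <- cbind(rows, vote_codes[p$kmer_id[i], ])
      votes[idx] <- votes[idx] + 1L
    }
    orig <- match(strsplit(seqs[r], "", fixed = TRUE)[[1]], c(DNA_BASES, "N"))
    top <- max.col(votes, ties.method = "first")
    mx <- votes[cbind(seq_len(L), top)]
    # ties keep the original base when it is among the argmax set
    keep_orig <- orig <= 4L & votes[cbind(seq_len(L), pmin(orig, 4L))] == mx
    new <- ifelse(mx == 0L | keep_orig, orig, top)
    if (any(new != orig)) {
      n_changed[r] <- sum(new != orig)
      seqs[r] <- paste(c(DNA_BASES, "N")[new], collapse = "")
    }
  }
  out <- reads
  out$seq <- seqs
  list(reads = out,
       outcome = tibble(read = seq_len(nrow(reads)), n_changed = n_changed,
                        changed = n_changed > 0L))
}

#' Trim low-quality read tails
#'
#' Optional post-correction step: removes trailing bases whose error
#' probability exceeds `10^(-min_phred/10)`. Sequence, probability and raw
#' quality fields are truncated together; reads that are entirely below
#' the cutoff become empty.
#'
#' @param reads A read tibble.
#' @param min_phred Phred threshold Q; bases worse than `10^(-Q/10)` are
#'   trimmed from the 3' end.
#' @return The trimmed read tibble.
#' @export
trim_reads <- function(reads, min_phred) {
  cutoff <- 10^(-min_phred / 10)
  keep_len <- map_int(reads$qual, function(q) {
    ok <- which(q <= cutoff)
    if (length(ok) == 0L) 0L else max(ok)
  })
  mutate(reads,
         seq = substr(.data$seq, 1L, keep_len),
         raw_qual = substr(.data$raw_qual, 1L, keep_len),
         qual = map2(.data$qual, keep_len, function(q, l) q[seq_len(l)]))
}
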