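#' Generate a random genome, optionally with diverged repeats
#'
#' Draws an i.i.d. genome at a given GC fraction. A `repeat_spec` plants
#' near-identical copies of one segment (a stated Hamming divergence apart)
#' at random non-overlapping locations, emulating genomic repeats whose
#' instances differ by a few substitutions — the situation that requires
#' subclustering rather than single-center component collapsing.
#'
#' @param length Genome length in bases.
#' @param gc_fraction Expected GC content (default 0.5).
#' @param repeat_spec Optional list with `n_copies`, `length`, `divergence`
#'   (substitutions between each extra copy and the template).
#' @param seed Integer seed; the genome is a pure function of its
#'   arguments.
#' @return A genome string; planted repeat locations are attached as the
#'   `repeats` attribute (tibble `start`, `end`, `copy_of`).
#' @export
make_genome <- function(length, gc_fraction = 0.5, repeat_spec = NULL,
                        seed = 1L) {
  stopifnot(length >= 1, gc_fraction > 0, gc_fraction < 1)
  set.seed(seed)
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2,
            gc_fraction / 2, (1 - gc_fraction) / 2)
  g <- sample(DNA_BASES, length, replace = TRUE, prob = prob)
  repeats <- tibble(start = integer(0), end = integer(0), copy_of = integer(0))
  if (!is.null(repeat_spec)) {
    rl <- repeat_spec$length
    nc <- repeat_spec$n_copies
    div <- repeat_spec$divergence
    if (nc * rl > length) abort("repeat_spec infeasible: copies exceed genome")
    # carve non-overlapping slots deterministically spaced across the genome
    slot_gap <- length %/% nc
    if (slot_gap < rl) abort("repeat_spec infeasible: copies overlap")
    starts <- (seq_len(nc) - 1L) * slot_gap + 1L
    template <- g[starts[1]:(starts[1] + rl - 1L)]
    for (i in seq_len(nc)[-1]) {
      copy <- template
      flip <- sample(rl, div)
      for (p in flip) copy[p] <- sample(setdiff(DNA_BASES, copy[p]), 1L)
      g[starts[i]:(starts[i] + rl - 1L)] <- copy
    }
    repeats <- tibble(start = starts, end = starts + rl - 1L,
                      copy_of = c(NA_integer_, rep(starts[1], nc - 1L)))
  }
  structure(paste(g, collapse = ""), repeats = repeats)
}

#' Simulate reads with amplification bias and quality-consistent errors
#'
#' Emulates the single-cell MDA regime: per-locus amplification weights are
#' lognormal (`sigma_coverage` is the sdlog; 0 gives uniform, multi-cell
#' like coverage), so realized coverage ranges over orders of magnitude.
#' Both strands are sampled. Per-base Phred scores are drawn around
#' `mean_phred` and errors are injected with exactly the probability the
#' emitted quality encodes (`10^(-Q/10)`), substituting uniformly among the
#' three alternative bases, so quality strings are honest estimates of the
#' true error process.
#'
#' @param genome Genome string from [make_genome()].
#' @param n_reads Number of reads.
#' @param read_len Read length (<= genome length).
#' @param sigma_coverage sdlog of the per-locus lognormal amplification
#'   weight (default 1.5, strongly non-uniform).
#' @param mean_phred,sd_phred Per-base quality distribution (integer Phred,
#'   clipped to [2, 40]); the default mean of 20 yields roughly 1%
#'   substitution errors.
#' @param error If FALSE, reads are exact genome substrings (qualities
#'   still emitted).
#' @param seed Integer seed.
#' @return List with `reads` (a read tibble) and `truth` (tibble `id`,
#'   `start` (1-based on the forward genome), `strand`, `true_seq` (the
#'   error-free read in read orientation), `error_offsets` (list column of
#'   0-based changed positions)).
#' @export
make_reads <- function(genome, n_reads, read_len, sigma_coverage = 1.5,
                       mean_phred = 20, sd_phred = 3, error = TRUE,
                       seed = 1L) {
  G <- nchar(genome)
  stopifnot(read_len <= G, n_reads >= 1)
  set.seed(seed)
  n_loci <- G - read_len + 1L
  w <- if (sigma_coverage > 0) {
    stats::rlnorm(n_loci, meanlog = 0, sdlog = sigma_coverage)
  } else rep(1, n_loci)
  starts <- sample.int(n_loci, n_reads, replace = TRUE, prob = w)
  strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
  true_fwd <- substring(genome, starts, starts + read_len - 1L)
  true_seq <- ifelse(strand == "+", true_fwd, revcomp(true_fwd))
  phred <- matrix(pmin(pmax(round(rnorm(n_reads * read_len, mean_phred,
                                        sd_phred)), 2L), 40L),
                  n_reads, read_len)
  raw_qual <- apply(phred, 1L, function(q) intToUtf8(q + 33L))
  err_p <- 10^(-phred / 10)
  seqs <- true_seq
  error_offsets <- vector("list", n_reads)
  if (error) {
    hit <- matrix(runif(n_reads * read_len) < err_p, n_reads, read_len)
    for (i in which(rowSums(hit) > 0L)) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      at <- which(hit[i, ])
      for (p in at) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
      seqs[i] <- paste(ch, collapse = "")
      error_offsets[[i]] <- at - 1L
    }
  }
  error_offsets[vapply(error_offsets, is.null, logical(1))] <- list(integer(0))
  ids <- sprintf("read_%06d", seq_len(n_reads))
  list(
    reads = read_table(ids, seqs, raw_qual),
    truth = tibble(id = ids, start = starts, strand = strand,
                   true_seq = true_seq, error_offsets = error_offsets))
}

#' Base error rate of reads against ground truth
#'
#' Fraction of bases differing from the error-free read sequence; the
#' before/after comparison used to evaluate correction.
#'
#' @param reads A read tibble (must align row-wise with `truth`).
#' @param truth Truth tibble from [make_reads()].
#' @return A single number, mismatching bases over total bases.
#' @export
base_error_rate <- function(reads, truth) {
  stopifnot(nrow(reads) == nrow(truth), all(reads$id == truth$id))
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
  }, reads$seq, truth$true_seq))
  mism / sum(nchar(truth$true_seq))
}

#' Write the ground truth table to TSV
#'
#' @param truth Truth tibble from [make_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_truth <- function(truth, path) {
  df <- mutate(truth,
               error_offsets = map_chr(.data$error_offsets,
                                       function(x) paste(x, collapse = ",")))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
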