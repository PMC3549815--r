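# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Default clamp keeping every error probability strictly inside (0, 1):
# products of probabilities are accumulated in log-space downstream, and an
# exact 0 or 1 would collapse them.
DEFAULT_CLAMP <- c(lo = 1e-10, hi = 1 - 1e-10)

clamp01 <- function(p, clamp = DEFAULT_CLAMP) {
  pmin(pmax(p, clamp[[1]]), clamp[[2]])
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `A/C/G/T/N` (N maps to N).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGTG", "TTAAN"))
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# k-mers as an n x k matrix of single characters; the workhorse layout for
# Hamming distances, consensus voting and likelihoods.
kmer_char_matrix <- function(kmers, k = NULL) {
  if (length(kmers) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = if (is.null(k)) 0 else k))
  }
  if (is.null(k)) k <- nchar(kmers[[1]])
  matrix(unlist(strsplit(kmers, "", fixed = TRUE), use.names = FALSE),
         nrow = length(kmers), ncol = k, byrow = TRUE)
}

# Map A/C/G/T characters to integers 1..4 (matrix in, matrix out).
base_codes <- function(chm) {
  codes <- match(chm, DNA_BASES)
  dim(codes) <- dim(chm)
  codes
}

# Stable polynomial string hash into 0..(n_buckets-1); must not vary across
# runs or platforms (reproducibility contract for the disk-bucketed counter).
stable_hash <- function(kmers, n_buckets) {
  if (length(kmers) == 0L) return(integer(0))
  k <- nchar(kmers[[1]])
  chm <- kmer_char_matrix(kmers, k)
  h <- rep(0, length(kmers))
  for (j in seq_len(k)) {
    h <- (h * 31 + match(chm[, j], c(DNA_BASES, "N"))) %% 2147483647
  }
  as.integer(h %% n_buckets)
}

# log(1 - exp(x)) for x < 0, stable near both ends.
log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}
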