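#' Hamming distance between equal-length strings
#'
#' Number of positions at which two strings differ. Vectorised over pairs
#' (the shorter argument is recycled).
#'
#' @param x,y Character vectors of equal-length strings.
#' @return Integer vector of distances.
#' @export
#' @examples
#' hamming_distance("ACGTG", "ACATG")
hamming_distance <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (any(nchar(x) != nchar(y))) abort("hamming_distance: length mismatch")
  mapply(function(a, b) {
    sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
  }, x, y, USE.NAMES = FALSE)
}

#' Index partitions for near-duplicate k-mer search
#'
#' Partitions the index set `{0, ..., k-1}` into `tau + 1` parts two ways.
#' By the pigeonhole principle, two k-mers at Hamming distance at most `tau`
#' must agree exactly on at least one part of any such partition, so equality
#' blocks under each part are sufficient candidate sets for distance-<= tau
#' pairs. The `contiguous` partition takes runs `{s*sigma, ..., s*sigma +
#' sigma - 1}`; the `strided` one takes `{s, s + tau + 1, s + 2(tau+1), ...}`.
#' When `tau + 1` does not divide `k`, part sizes differ by at most one,
#' which preserves the pigeonhole guarantee verbatim.
#'
#' @param k k-mer length.
#' @param tau Maximum Hamming distance (>= 1).
#' @return List with elements `contiguous` and `strided`, each a list of
#'   `tau + 1` integer vectors of 0-based indices.
#' @export
#' @examples
#' make_partitions(9, 2)
make_partitions <- function(k, tau) {
  stopifnot(tau >= 1L)
  if (tau + 1L > k) abort("make_partitions: tau + 1 exceeds k")
  sizes <- rep(k %/% (tau + 1L), tau + 1L)
  extra <- k %% (tau + 1L)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  contiguous <- lapply(seq_len(tau + 1L), function(s) {
    (ends[s] - sizes[s]):(ends[s] - 1L)
  })
  strided <- lapply(seq_len(tau + 1L) - 1L, function(s) {
    seq(s, k - 1L, by = tau + 1L)
  })
  list(contiguous = contiguous, strided = strided)
}

#' Equality blocks of k-mers under an index partition
#'
#' For each part `I` of the partition, groups k-mers whose subsequences at
#' the indices in `I` are identical. Singleton blocks are dropped (they
#' contribute no candidate pairs). A k-mer may appear in blocks of several
#' parts.
#'
#' @param kmers Character vector of equal-length k-mers.
#' @param partition A list of integer vectors of 0-based indices (one
#'   element of the result of [make_partitions()]).
#' @param ids Optional integer ids to emit instead of positions in `kmers`.
#' @return List of integer vectors, each a block of size >= 2.
#' @export
find_blocks <- function(kmers, partition, ids = seq_along(kmers)) {
  out <- list()
  for (part in partition) {
    key <- do.call(paste0, lapply(part + 1L, function(p) substr(kmers, p, p)))
    grp <- split(ids, key)
    out <- c(out, unname(grp[lengths(grp) >= 2L]))
  }
  out
}

#' Connected components of the Hamming graph
#'
#' Computes the connected components of the graph on `kmers` whose edges
#' join pairs at Hamming distance at most `tau`, without comparing all
#' pairs: k-mers are first grouped into equality blocks under the
#' contiguous index partition; any block larger than `max_quadratic` is
#' re-split under the strided partition; all resulting blocks are processed
#' exhaustively (pairwise distances, union-find merges). The result equals
#' the brute-force all-pairs components for every input and is independent
#' of `max_quadratic` and of input order (up to component numbering, which
#' is by smallest member index).
#'
#' @param kmers Character vector of distinct equal-length k-mers, or a
#'   `kmer_index`.
#' @param tau Maximum Hamming distance defining edges (default 1).
#' @param max_quadratic Blocks above this size are re-split with the strided
#'   partition before exhaustive processing (default 1000).
#' @return Integer vector `membership`: for each k-mer, its component id.
#'   Components are numbered 1, 2, ... by their smallest member index.
#' @export
#' @examples
#' X <- c("ACGTG", "CGTGT", "GTGTG", "ACATG", "CATGT",
#'        "ATGTG", "ACCTG", "CCTGT", "CTGTC")
#' table(hamming_components(X, tau = 1))
hamming_components <- function(kmers, tau = 1L, max_quadratic = 1000L) {
  if (inherits(kmers, "kmer_index")) kmers <- kmers$kmers
  stopifnot(tau >= 1L, max_quadratic >= 2L)
  n <- length(kmers)
  if (n == 0L) return(integer(0))
  k <- nchar(kmers[[1]])
  parts <- make_partitions(k, tau)
  # union-find with path halving + union by size
  parent <- seq_len(n)
  size <- rep(1L, n)
  uf_find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  uf_union <- function(a, b) {
    ra <- uf_find(a); rb <- uf_find(b)
    if (ra == rb) return(invisible())
    if (size[ra] < size[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
    parent[rb] <<- ra
    size[ra] <<- size[ra] + size[rb]
    invisible()
  }
  # n x k byte matrix for fast row-vs-rows distances
  bytes <- matrix(charToRaw(paste(kmers, collapse = "")), ncol = k, byrow = TRUE)
  process_exhaustively <- function(block) {
    b <- length(block)
    for (i in seq_len(b - 1L)) {
      rest <- block[(i + 1L):b]
      d <- rowSums(bytes[rest, , drop = FALSE] !=
                     matrix(bytes[block[i], ], nrow = b - i, ncol = k, byrow = TRUE))
      for (j in rest[d <= tau]) uf_union(block[i], j)
    }
  }
  for (block in find_blocks(kmers, parts$contiguous)) {
    if (length(block) > max_quadratic) {
      for (sub in find_blocks(kmers[block], parts$strided, ids = block)) {
        process_exhaustively(sub)
      }
    } else {
      process_exhaustively(block)
    }
  }
  roots <- vapply(seq_len(n), uf_find, integer(1))
  match(roots, unique(roots[order(seq_len(n))]))  # number by smallest member
}

#' Components as a list of member id sets
#'
#' @param membership Integer vector from [hamming_components()].
#' @return List of integer vectors, ordered by component id.
#' @export
component_members <- function(membership) {
  unname(split(seq_along(membership), membership))
}

#' Write components to TSV (component id, size, members)
#'
#' @param membership Integer membership vector.
#' @param kmers The k-mer strings the membership refers to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_components <- function(membership, kmers, path) {
  comps <- component_members(membership)
  df <- data.frame(
    component = seq_along(comps),
    size = lengths(comps),
    members = vapply(comps, function(m) paste(kmers[m], collapse = ","), character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
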