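#' Probability that a k-mer is error-free
#'
#' `p_x = prod_j (1 - q_x[j])` over the combined per-position error
#' probabilities of the k-mer (products over all of its occurrences),
#' computed in log-space.
#'
#' @param index A `kmer_index`.
#' @param clamp Probability clamp applied to the per-position products.
#' @return Numeric vector, one probability per distinct k-mer.
#' @export
kmer_quality <- function(index, clamp = DEFAULT_CLAMP) {
  q <- error_profile(index, clamp)
  if (nrow(q) == 0L) return(numeric(0))
  exp(rowSums(log1p(-q)))
}

#' Probability that a cluster contains at least one correct k-mer
#'
#' `p_C = 1 - prod_{x in C} (1 - p_x)`. Singletons are deliberately not
#' special-cased: a lone k-mer competes on the same footing as a chance
#' cluster of several low-quality k-mers.
#'
#' @param p Numeric vector of member probabilities `p_x`.
#' @return The cluster quality, a single probability.
#' @export
#' @examples
#' cluster_quality(c(0.5, 0.5))  # 0.75
cluster_quality <- function(p) {
  if (length(p) == 0L) abort("cluster_quality: empty cluster")
  -expm1(sum(log1p(-p)))
}

#' Select solid k-mers from subcluster centers
#'
#' Marks as solid the centers of subclusters whose cluster quality `p_C`
#' exceeds `threshold`. Consensus centers that do not occur in the reads
#' are appended to the k-mer universe with a synthetic quality derived from
#' the members' per-position error products at positions agreeing with the
#' center; such centers can vote during correction but never provide read
#' coverage during expansion (coverage is defined over observed
#' occurrences).
#'
#' @param sc A `subclustering` object.
#' @param index The `kmer_index` the subclustering refers to.
#' @param threshold Solidness threshold on `p_C` in (0, 1); default
#'   `1 - 1e-3` (strict).
#' @param clamp Probability clamp.
#' @return A `solid_set`: list with `kmers` (observed k-mers then novel
#'   centers), `observed` (logical), `solid` (logical, grows during
#'   expansion), `center_of` (integer: every k-mer's subcluster center, as
#'   an index into `kmers`), `p_correct` (per k-mer), and `clusters` (the
#'   cluster table with `p_C` and solidness).
#' @export
select_solid <- function(sc, index, threshold = 1 - 1e-3,
                         clamp = DEFAULT_CLAMP) {
  stopifnot(threshold > 0, threshold < 1)
  n_obs <- length(index$kmers)
  p_x <- kmer_quality(index, clamp)
  cl <- sc$assignments$cluster
  p_C <- vapply(split(p_x[sc$assignments$kmer_id], cl), cluster_quality,
                numeric(1))
  clusters <- mutate(sc$clusters, p_C = as.numeric(p_C[as.character(.data$cluster)]),
                     solid_center = .data$p_C > threshold)
  # map centers into the k-mer universe, appending unobserved centers
  center_idx <- match(clusters$center, index$kmers)
  novel <- which(is.na(center_idx))
  novel_kmers <- clusters$center[novel]
  dup <- match(novel_kmers, unique(novel_kmers))
  uniq_novel <- unique(novel_kmers)
  center_idx[novel] <- n_obs + dup
  # synthetic p_x for unobserved centers: per-position products over members
  # agreeing with the center at that position
  p_novel <- numeric(length(uniq_novel))
  if (length(uniq_novel) > 0L) {
    q <- error_profile(index, clamp)
    for (i in seq_along(uniq_novel)) {
      ci <- novel[dup == i][1L]
      members <- sc$assignments$kmer_id[cl == clusters$cluster[ci]]
      mcodes <- base_codes(kmer_char_matrix(index$kmers[members], index$k))
      ccode <- base_codes(kmer_char_matrix(uniq_novel[i], index$k))[1L, ]
      agree <- mcodes == matrix(ccode, nrow = length(members), ncol = index$k,
                                byrow = TRUE)
      lq <- log(q[members, , drop = FALSE])
      lq[!agree] <- 0
      qc <- clamp01(exp(colSums(lq)), clamp)
      p_novel[i] <- exp(sum(log1p(-qc)))
    }
  }
  kmers_ext <- c(index$kmers, uniq_novel)
  solid <- rep(FALSE, length(kmers_ext))
  solid_centers <- center_idx[clusters$solid_center]
  solid[solid_centers] <- TRUE
  center_of <- c(center_idx[cl[order(sc$assignments$kmer_id)]],
                 (n_obs + seq_along(uniq_novel)))
  structure(
    list(kmers = kmers_ext, observed = c(rep(TRUE, n_obs),
                                         rep(FALSE, length(uniq_novel))),
         solid = solid, center_of = center_of,
         p_correct = c(p_x, p_novel), clusters = clusters),
    class = "solid_set")
}

#' @export
print.solid_set <- function(x, ...) {
  cat(sprintf("<solid_set> %d/%d k-mers solid (%d unobserved centers)\n",
              sum(x$solid), length(x$solid), sum(!x$observed)))
  invisible(x)
}

#' Iteratively expand the solid set over fully covered reads
#'
#' A read is completely covered when every one of its positions lies inside
#' at least one occurrence of a solid k-mer in that read. All valid k-mers
#' of a completely covered read are marked solid, and the pass over the
#' reads repeats until no k-mer is added (a fixed point, reached in at most
#' as many passes as there are distinct k-mers; in practice a handful).
#' The solid set only grows, and the fixed point does not depend on read
#' order.
#'
#' @param reads The read tibble.
#' @param solid A `solid_set` from [select_solid()].
#' @param index The `kmer_index` (provides occurrence positions).
#' @return The `solid_set` with an enlarged `solid` slot.
#' @export
expand_solid <- function(reads, solid, index) {
  pos <- index$positions
  if (nrow(pos) == 0L) return(solid)
  L <- nchar(reads$seq)
  k <- index$k
  repeat {
    sp <- pos[solid$solid[pos$kmer_id], ]
    if (nrow(sp) == 0L) break
    cov <- sp |>
      group_by(.data$read) |>
      summarise(first = min(.data$offset), last = max(.data$offset),
                gap = if (n() > 1L) max(diff(sort(.data$offset))) else 0L,
                .groups = "drop")
    covered <- cov$read[cov$first == 0L &
                          cov$last == L[cov$read] - k &
                          cov$gap <= k]
    new_ids <- unique(pos$kmer_id[pos$read %in% covered])
    new_ids <- new_ids[!solid$solid[new_ids]]
    if (length(new_ids) == 0L) break
    solid$solid[new_ids] <- TRUE
  }
  solid
}
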