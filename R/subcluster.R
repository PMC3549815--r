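#' Fixed-error-rate log-likelihood of one k-mer given another
#'
#' The single-parameter generative model in which every position is
#' independently erroneous with the same probability `epsilon`:
#' `L(x|y) = (1-eps)^(k-d) * eps^d` for `d = hamming_distance(x, y)`.
#' Returned in log-space. Used by the emulation mode that bypasses
#' quality-aware subclustering; the quality-weighted model is
#' [kmer_log_likelihood()].
#'
#' @param x,y Equal-length k-mers.
#' @param epsilon Per-position error probability in (0, 1); default 0.01.
#' @return Log-likelihood (natural log).
#' @export
hammer_likelihood <- function(x, y, epsilon = 0.01) {
  stopifnot(epsilon > 0, epsilon < 1)
  if (nchar(x) != nchar(y)) abort("hammer_likelihood: length mismatch")
  d <- hamming_distance(x, y)
  (nchar(x) - d) * log1p(-epsilon) + d * log(epsilon)
}

#' Quality-weighted log-likelihood of a k-mer given a center
#'
#' Under independent per-position errors with combined error probabilities
#' `q_x[j]` (the product over the k-mer's occurrences of per-base error
#' probabilities, see [error_profile()]), the likelihood that `x` was
#' generated from center `c` is the product of `q_x[j]` over disagreeing
#' positions and `1 - q_x[j]` over agreeing ones.
#'
#' @param x,cent Equal-length k-mer strings.
#' @param q Numeric vector of length k, the combined error probabilities of
#'   `x` at each position.
#' @return Log-likelihood (natural log).
#' @export
kmer_log_likelihood <- function(x, cent, q) {
  if (nchar(x) != nchar(cent)) abort("kmer_log_likelihood: length mismatch")
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  cs <- strsplit(cent, "", fixed = TRUE)[[1]]
  mism <- xs != cs
  sum(log(q[mism])) + sum(log1p(-q[!mism]))
}

# Vectorised core: rows of code matrix vs one center code vector.
# codes: n x k integer (1..4); cent_codes: length k; logq/log1mq: n x k.
row_log_likelihood <- function(codes, cent_codes, logq, log1mq) {
  mism <- codes != matrix(cent_codes, nrow = nrow(codes), ncol = length(cent_codes),
                          byrow = TRUE)
  rowSums(ifelse(mism, logq, log1mq))
}

#' Consensus center of a set of k-mers
#'
#' Position-wise weighted majority: each member votes with weight equal to
#' its multiplicity `count_x` (multiset semantics), ties broken in fixed
#' alphabet order A < C < G < T. This is the maximum-likelihood center
#' under the independent-error model.
#'
#' @param kmers Character vector of member k-mers.
#' @param weight Numeric vote weights (default all 1).
#' @return The consensus k-mer string.
#' @export
#' @examples
#' consensus_center(c("ACGTG", "ACATG", "ATGTG"))
consensus_center <- function(kmers, weight = rep(1, length(kmers))) {
  if (length(kmers) == 0L) abort("consensus_center: empty member set")
  codes <- base_codes(kmer_char_matrix(kmers))
  consensus_from_codes(codes, weight)
}

consensus_from_codes <- function(codes, weight) {
  k <- ncol(codes)
  score <- vapply(1:4, function(b) colSums(weight * (codes == b)), numeric(k))
  if (k == 1L) dim(score) <- c(1L, 4L)
  paste(DNA_BASES[max.col(score, ties.method = "first")], collapse = "")
}

#' BIC-penalized clustering objective
#'
#' The model-selection score for a subclustering into `m` parts:
#' `2 * log L_m - (3km + m - 1) * log N`, natural logs throughout. The
#' likelihood `L_m` multiplies [kmer_log_likelihood()] terms of every member
#' against its cluster center, each weighted by the member's multiplicity
#' (every read occurrence is an observation). The parameter count `3km + m
#' - 1` charges `km` for centers, `2km` for conditional substitution
#' probabilities, and `m - 1` for cluster proportions. `N` defaults to the
#' total multiset size of the component (sum of counts); set
#' `distinct = TRUE` to read the observation count as the number of
#' distinct k-mers instead.
#'
#' @param members Integer ids of the component's k-mers (rows of `index`).
#' @param assign Integer cluster assignment (1..m) per member.
#' @param centers Character vector of m center k-mers.
#' @param index A `kmer_index`.
#' @param profile Error-probability matrix from [error_profile()].
#' @param distinct Count observations as distinct k-mers rather than total
#'   multiplicity.
#' @return The scalar objective (higher is better).
#' @export
bic_objective <- function(members, assign, centers, index, profile,
                          distinct = FALSE) {
  stopifnot(length(members) > 0L, length(assign) == length(members))
  k <- index$k
  m <- length(centers)
  w <- index$count[members]
  codes <- base_codes(kmer_char_matrix(index$kmers[members], k))
  q <- profile[members, , drop = FALSE]
  logq <- log(q); log1mq <- log1p(-q)
  loglik <- 0
  for (i in seq_len(m)) {
    sel <- which(assign == i)
    if (length(sel) == 0L) next
    cc <- base_codes(matrix(strsplit(centers[i], "", fixed = TRUE)[[1]], 1L))[1L, ]
    ll <- row_log_likelihood(codes[sel, , drop = FALSE], cc,
                             logq[sel, , drop = FALSE], log1mq[sel, , drop = FALSE])
    loglik <- loglik + sum(w[sel] * ll)
  }
  n_obs <- if (distinct) length(members) else sum(w)
  2 * loglik - (3 * k * m + m - 1) * log(n_obs)
}

#' m-means clustering of a component under Hamming distance
#'
#' Lloyd-style alternation specialised to strings: initial centers are the
#' `m` members with the highest probability of being error-free (ties by
#' higher multiplicity, then lexicographic order); each member is assigned
#' to the nearest center by Hamming distance (ties to the lowest center
#' index); centers are recomputed as multiplicity-weighted consensus
#' strings. A cluster left empty is reseeded with the member farthest from
#' its currently assigned center. Stops when assignments repeat or after
#' `max_iter` rounds.
#'
#' @param members Integer k-mer ids forming the component.
#' @param m Number of clusters, `1 <= m <= length(members)`.
#' @param index A `kmer_index`.
#' @param profile Error-probability matrix from [error_profile()].
#' @param max_iter Iteration cap (default 100).
#' @return List with `assign` (integer per member), `centers` (character
#'   vector of length m).
#' @export
m_means <- function(members, m, index, profile, max_iter = 100L) {
  n <- length(members)
  if (m < 1L || m > n) abort("m_means: m out of range")
  kmers <- index$kmers[members]
  w <- index$count[members]
  codes <- base_codes(kmer_char_matrix(kmers, index$k))
  if (m == 1L) {
    return(list(assign = rep(1L, n), centers = consensus_from_codes(codes, w)))
  }
  # least error probability = highest p_x; ties: higher count, then lexicographic
  p <- exp(rowSums(log1p(-profile[members, , drop = FALSE])))
  init_ord <- order(-p, -w, kmers, method = "radix")
  centers <- kmers[init_ord[seq_len(m)]]
  assign <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    cent_codes <- base_codes(kmer_char_matrix(centers, index$k))
    D <- vapply(seq_len(m), function(i) {
      rowSums(codes != matrix(cent_codes[i, ], nrow = n, ncol = index$k,
                              byrow = TRUE))
    }, numeric(n))
    if (n == 1L) dim(D) <- c(1L, m)
    new_assign <- max.col(-D, ties.method = "first")
    # reseed empty clusters with the member farthest from its center
    repeat {
      empty <- setdiff(seq_len(m), unique(new_assign))
      if (length(empty) == 0L) break
      cur_d <- D[cbind(seq_len(n), new_assign)]
      far <- which.max(cur_d)
      new_assign[far] <- empty[1L]
      D[far, ] <- Inf; D[far, empty[1L]] <- 0  # pin the reseeded member
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    centers <- vapply(seq_len(m), function(i) {
      sel <- assign == i
      consensus_from_codes(codes[sel, , drop = FALSE], w[sel])
    }, character(1))
  }
  list(assign = assign, centers = centers)
}

#' Subcluster one Hamming component by penalized model selection
#'
#' Sweeps `m = 1, 2, 3, ...`, clustering with [m_means()] and scoring with
#' [bic_objective()]; stops at the first `m` whose objective fails to
#' improve and returns the clustering for `m - 1`. Singleton components
#' return immediately with one cluster.
#'
#' @inheritParams m_means
#' @param distinct Passed to [bic_objective()].
#' @return List with `assign`, `centers`, `m`, and `objective` (the
#'   retained clustering's score).
#' @export
subcluster_component <- function(members, index, profile, max_iter = 100L,
                                 distinct = FALSE) {
  stopifnot(length(members) > 0L)
  best <- m_means(members, 1L, index, profile, max_iter)
  best_obj <- bic_objective(members, best$assign, best$centers, index, profile,
                            distinct)
  m <- 1L
  while (m < length(members)) {
    m <- m + 1L
    cand <- m_means(members, m, index, profile, max_iter)
    obj <- bic_objective(members, cand$assign, cand$centers, index, profile,
                         distinct)
    if (obj <= best_obj) break
    best <- cand
    best_obj <- obj
  }
  list(assign = best$assign, centers = best$centers,
       m = length(best$centers), objective = best_obj)
}

#' Subcluster every component of a k-mer index
#'
#' Runs [subcluster_component()] over all Hamming components (or, in
#' emulation mode, assigns each component a single consensus center without
#' model selection) and returns a flat cluster table.
#'
#' @param index A `kmer_index`.
#' @param membership Integer component membership from
#'   [hamming_components()].
#' @param hammer_emulate If TRUE, skip Bayesian subclustering: one cluster
#'   per component with its consensus as center.
#' @param distinct,max_iter See [subcluster_component()].
#' @return A `subclustering` object: list with `assignments` (tibble
#'   `kmer_id`, `component`, `cluster`), `clusters` (tibble `cluster`,
#'   `component`, `center`, `n_members`, `total_count`) and `components`
#'   (tibble `component`, `m`, `objective`).
#' @export
subcluster_components <- function(index, membership, hammer_emulate = FALSE,
                                  distinct = FALSE, max_iter = 100L) {
  if (length(membership) == 0L) {
    return(structure(
      list(assignments = tibble(kmer_id = integer(0), component = integer(0),
                                cluster = integer(0)),
           clusters = tibble(cluster = integer(0), component = integer(0),
                             center = character(0), n_members = integer(0),
                             total_count = integer(0)),
           components = tibble(component = integer(0), m = integer(0),
                               objective = numeric(0))),
      class = "subclustering"))
  }
  profile <- error_profile(index)
  comps <- component_members(membership)
  n_comp <- length(comps)
  assign_all <- integer(length(membership))
  centers_list <- vector("list", n_comp)
  m_vec <- integer(n_comp)
  obj_vec <- numeric(n_comp)
  cluster_base <- 0L
  cluster_of <- integer(length(membership))
  for (ci in seq_len(n_comp)) {
    members <- comps[[ci]]
    if (length(members) == 1L) {
      res <- list(assign = 1L, centers = index$kmers[members], m = 1L,
                  objective = NA_real_)
      if (!hammer_emulate) {
        res$objective <- bic_objective(members, 1L, res$centers, index,
                                       profile, distinct)
      }
    } else if (hammer_emulate) {
      res <- list(assign = rep(1L, length(members)),
                  centers = consensus_center(index$kmers[members],
                                             index$count[members]),
                  m = 1L, objective = NA_real_)
    } else {
      res <- subcluster_component(members, index, profile, max_iter, distinct)
    }
    assign_all[members] <- res$assign + cluster_base
    cluster_of[members] <- res$assign
    centers_list[[ci]] <- res$centers
    m_vec[ci] <- res$m
    obj_vec[ci] <- res$objective
    cluster_base <- cluster_base + res$m
  }
  centers <- unlist(centers_list, use.names = FALSE)
  assignments <- tibble(kmer_id = seq_along(membership),
                        component = membership, cluster = assign_all)
  clusters <- assignments |>
    group_by(.data$cluster, .data$component) |>
    summarise(n_members = n(),
              total_count = sum(index$count[.data$kmer_id]),
              .groups = "drop") |>
    arrange(.data$cluster) |>
    mutate(center = centers[.data$cluster]) |>
    select("cluster", "component", "center", "n_members", "total_count")
  structure(
    list(assignments = assignments, clusters = clusters,
         components = tibble(component = seq_len(n_comp), m = m_vec,
                             objective = obj_vec)),
    class = "subclustering")
}

#' @export
print.subclustering <- function(x, ...) {
  cat(sprintf("<subclustering> %d k-mers in %d components -> %d subclusters\n",
              nrow(x$assignments), nrow(x$components), nrow(x$clusters)))
  invisible(x)
}

#' @rdname subcluster_components
#' @param x A `subclustering` object.
#' @param ... Unused.
#' @export
tidy.subclustering <- function(x, ...) x$clusters

#' Write the subcluster table to TSV
#'
#' @param sc A `subclustering` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_subclusters <- function(sc, path) {
  df <- left_join(sc$clusters, sc$components, by = "component")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
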