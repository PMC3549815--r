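#' Enumerate the valid k-mers of a sequence
#'
#' Yields every length-`k` substring that contains no `N`, with its 0-based
#' offset. Sequences shorter than `k` yield an empty table.
#'
#' @param seq A single sequence string over A/C/G/T/N.
#' @param k k-mer length.
#' @return Tibble with columns `offset` (0-based) and `kmer`.
#' @export
#' @examples
#' enumerate_kmers("ACGTGTG", 5)
enumerate_kmers <- function(seq, k) {
  stopifnot(length(seq) == 1L, k >= 1L)
  L <- nchar(seq)
  if (L < k) return(tibble(offset = integer(0), kmer = character(0)))
  starts <- valid_kmer_starts(seq, k)
  if (length(starts) == 0L) {
    return(tibble(offset = integer(0), kmer = character(0)))
  }
  tibble(offset = starts - 1L, kmer = substring(seq, starts, starts + k - 1L))
}

# 1-based start positions of N-free k-mer windows.
valid_kmer_starts <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(integer(0))
  starts <- seq_len(L - k + 1L)
  npos <- gregexpr("N", seq, fixed = TRUE)[[1]]
  if (npos[1] != -1L) {
    isn <- integer(L)
    isn[npos] <- 1L
    cs <- cumsum(isn)
    starts <- starts[cs[starts + k - 1L] - cs[starts] + isn[starts] == 0L]
  }
  starts
}

# Shared occurrence scan: one row per N-free k-mer occurrence, with the
# aligned per-position log error probabilities.
kmer_occurrences <- function(reads, k, canonical = FALSE) {
  L <- nchar(reads$seq)
  base_off <- cumsum(c(0, L))
  starts <- lapply(seq_len(nrow(reads)), function(i) valid_kmer_starts(reads$seq[i], k))
  n_per_read <- lengths(starts)
  occ_read <- rep(seq_len(nrow(reads)), n_per_read)
  occ_start <- unlist(starts, use.names = FALSE)
  if (length(occ_start) == 0L) {
    return(list(read = integer(0), offset = integer(0), kmer = character(0),
                logq = matrix(numeric(0), 0, k)))
  }
  occ_kmer <- substring(reads$seq[occ_read], occ_start, occ_start + k - 1L)
  logq_all <- log(unlist(reads$qual, use.names = FALSE))
  idx <- outer(base_off[occ_read] + occ_start, 0:(k - 1L), "+")
  occ_logq <- matrix(logq_all[idx], nrow = length(occ_start), ncol = k)
  if (canonical) {
    rc <- revcomp(occ_kmer)
    flip <- rc < occ_kmer
    if (any(flip)) {
      occ_kmer[flip] <- rc[flip]
      occ_logq[flip, ] <- occ_logq[flip, k:1, drop = FALSE]
    }
  }
  list(read = occ_read, offset = occ_start - 1L, kmer = occ_kmer, logq = occ_logq)
}

new_kmer_index <- function(k, kmers, count, log_error, positions, n_reads,
                           canonical = FALSE) {
  structure(
    list(k = k, kmers = kmers, count = count, log_error = log_error,
         positions = positions, n_reads = n_reads, canonical = canonical),
    class = "kmer_index")
}

#' Collect per-k-mer statistics from reads
#'
#' Step (1) of the correction pipeline. Every N-free k-mer occurrence is
#' enumerated and, per distinct k-mer `x`, three statistics are aggregated:
#' the multiplicity `count_x`; the per-position log products of error
#' probabilities over all occurrences (`log_error`, a count-weighted
#' k-vector per k-mer); and from these the probability that the k-mer is
#' error-free (see [kmer_quality()]). Per-read occurrence positions are
#' recorded so later stages never rescan the reads.
#'
#' @param reads A read tibble (see [read_table()]).
#' @param k k-mer length (default 21).
#' @param canonical If TRUE, each k-mer is mapped to the lexicographic
#'   minimum of itself and its reverse complement (strands merged); off by
#'   default, matching the substitution-error model which treats strands
#'   independently.
#' @return A `kmer_index`: distinct k-mers in lexicographic order, their
#'   statistics, and an occurrence table `positions` with columns `read`
#'   (row index into `reads`), `offset` (0-based) and `kmer_id`.
#' @export
collect_statistics <- function(reads, k = 21L, canonical = FALSE) {
  occ <- kmer_occurrences(reads, k, canonical)
  if (length(occ$kmer) == 0L) {
    return(new_kmer_index(k, character(0), integer(0),
                          matrix(numeric(0), 0, k),
                          tibble(read = integer(0), offset = integer(0),
                                 kmer_id = integer(0)),
                          nrow(reads), canonical))
  }
  f <- factor(occ$kmer)
  id <- as.integer(f)
  positions <- tibble(read = occ$read, offset = occ$offset, kmer_id = id)
  positions <- arrange(positions, .data$read, .data$offset)
  log_error <- rowsum(occ$logq, id, reorder = TRUE)
  dimnames(log_error) <- NULL
  new_kmer_index(k, levels(f), tabulate(id, nbins = nlevels(f)),
                 log_error, positions, nrow(reads), canonical)
}

#' Count k-mers through hash-bucketed spill files
#'
#' Disk-backed alternative to [collect_statistics()] for inputs whose
#' distinct k-mer set does not fit in memory: each occurrence is hashed by
#' its k-mer into one of `n_files` spill files, each file is sorted
#' lexicographically and aggregated in a single sequential scan, and the
#' per-bucket tables are merged. The result is identical to the in-memory
#' path (bit-equal counts; log aggregates to within 1e-9, the spill files
#' being decimal text).
#'
#' @inheritParams collect_statistics
#' @param n_files Number of spill files (>= 1).
#' @param workdir Writable scratch directory.
#' @return A `kmer_index`.
#' @export
bucketed_count <- function(reads, k = 21L, n_files = 16L, workdir = tempdir(),
                           canonical = FALSE) {
  stopifnot(n_files >= 1L)
  if (!dir.exists(workdir)) {
    abort(sprintf("workdir '%s' does not exist", workdir))
  }
  occ <- kmer_occurrences(reads, k, canonical)
  empty <- length(occ$kmer) == 0L
  bucket <- if (empty) integer(0) else stable_hash(occ$kmer, n_files)
  files <- file.path(workdir, sprintf("kmer_bucket_%04d.tsv", seq_len(n_files) - 1L))
  on.exit(unlink(files), add = TRUE)
  for (b in seq_len(n_files) - 1L) {
    sel <- which(bucket == b)
    df <- data.frame(kmer = occ$kmer[sel], read = occ$read[sel],
                     offset = occ$offset[sel])
    if (length(sel) > 0L) {
      df <- cbind(df, format(occ$logq[sel, , drop = FALSE], digits = 17))
    } else {
      df <- cbind(df, matrix(character(0), 0, k))
    }
    write.table(df, files[b + 1L], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  parts <- lapply(files, function(f) {
    df <- tryCatch(
      read.table(f, sep = "\t", colClasses = c("character", "integer", "integer",
                                               rep("numeric", k))),
      error = function(e) NULL)
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    df <- df[order(df[[1]], method = "radix"), , drop = FALSE]  # lexicographic sort
    r <- rle(df[[1]])
    gid <- rep(seq_along(r$values), r$lengths)
    list(kmers = r$values, count = r$lengths,
         log_error = rowsum(as.matrix(df[, 3L + seq_len(k)]), gid, reorder = TRUE),
         occ = data.frame(read = df[[2]], offset = df[[3]], kmer = df[[1]]))
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) {
    return(new_kmer_index(k, character(0), integer(0), matrix(numeric(0), 0, k),
                          tibble(read = integer(0), offset = integer(0),
                                 kmer_id = integer(0)), nrow(reads), canonical))
  }
  kmers <- unlist(lapply(parts, `[[`, "kmers"), use.names = FALSE)
  ord <- order(kmers, method = "radix")
  kmers <- kmers[ord]
  count <- unlist(lapply(parts, `[[`, "count"), use.names = FALSE)[ord]
  log_error <- do.call(rbind, lapply(parts, `[[`, "log_error"))[ord, , drop = FALSE]
  dimnames(log_error) <- NULL
  occ_df <- do.call(rbind, lapply(parts, `[[`, "occ"))
  positions <- tibble(read = occ_df$read, offset = occ_df$offset,
                      kmer_id = match(occ_df$kmer, kmers))
  positions <- arrange(positions, .data$read, .data$offset)
  new_kmer_index(k, kmers, as.integer(count), log_error, positions,
                 nrow(reads), canonical)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d: %d distinct k-mers, %d occurrences over %d reads%s\n",
              x$k, length(x$kmers), nrow(x$positions), x$n_reads,
              if (x$canonical) " (canonical)" else ""))
  invisible(x)
}

#' Combined per-position error probabilities
#'
#' Returns the matrix `q_x[j]`: for each distinct k-mer, the product over
#' its occurrences of the per-base error probabilities at position `j`
#' (clamped strictly inside (0,1)). A multiset of occurrences agreeing on a
#' nucleotide is erroneous there with exactly this product.
#'
#' @param index A `kmer_index`.
#' @param clamp Probability clamp.
#' @return Numeric matrix, k-mers by positions.
#' @export
error_profile <- function(index, clamp = DEFAULT_CLAMP) {
  clamp01(exp(index$log_error), clamp)
}

#' Tidy per-k-mer statistics table
#'
#' @param index A `kmer_index`.
#' @param per_position If TRUE, adds a `q` list column with the k
#'   per-position combined error probabilities.
#' @return Tibble with columns `kmer_id`, `kmer`, `count`, `p_correct`
#'   (probability the k-mer is error-free) and `quality` (its complement,
#'   the probability of at least one sequencing error in the k-mer).
#' @export
kmer_table <- function(index, per_position = FALSE) {
  p <- kmer_quality(index)
  out <- tibble(kmer_id = seq_along(index$kmers), kmer = index$kmers,
                count = index$count, p_correct = p, quality = 1 - p)
  if (per_position) {
    q <- error_profile(index)
    out$q <- lapply(seq_len(nrow(q)), function(i) q[i, ])
  }
  out
}

#' Write the k-mer statistics table to TSV
#'
#' Columns: kmer, count, p_correct, quality, then the k per-position
#' combined error products.
#'
#' @param index A `kmer_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_kmer_table <- function(index, path) {
  tab <- kmer_table(index)
  q <- error_profile(index)
  colnames(q) <- paste0("q", seq_len(ncol(q)) - 1L)
  write.table(cbind(tab[, c("kmer", "count", "p_correct", "quality")], q),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
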