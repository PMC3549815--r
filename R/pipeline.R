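#' Pipeline configuration
#'
#' Bundles and validates every tunable of the correction pipeline.
#'
#' @param k k-mer length (default 21).
#' @param tau Hamming graph edge threshold (default 1; 1 or 2 supported).
#' @param solid_threshold Cluster quality `p_C` above which a center is
#'   solid; default `1 - 1e-3`.
#' @param max_iterations Maximum correction iterations (default 3).
#' @param change_fraction_stop Stop when the fraction of reads changed in
#'   an iteration falls below this (default 0.002).
#' @param phred_offset 33 or 64.
#' @param epsilon Error rate of the fixed-rate likelihood used by
#'   emulation mode (default 0.01).
#' @param max_quadratic Block size above which the strided partition
#'   re-splits (default 1000).
#' @param canonical Merge reverse-complement strands of k-mers.
#' @param hammer_emulate Skip Bayesian subclustering (one consensus center
#'   per Hamming component).
#' @param no_expansion Skip the solid-set expansion step; together with
#'   `hammer_emulate` this reproduces the plain component-center corrector.
#' @param bic_distinct Count BIC observations as distinct k-mers rather
#'   than total multiplicity.
#' @param trim_quality If non-NULL, Phred threshold for 3' quality
#'   trimming applied after the final iteration (default off; core
#'   correction preserves read length).
#' @param n_files If non-NULL, use the disk-bucketed k-mer counter with
#'   this many spill files.
#' @param workdir Scratch directory for the bucketed counter.
#' @param seed Integer seed recorded for provenance; the pipeline itself is
#'   deterministic.
#' @return A `correction_config` list.
#' @export
correction_config <- function(k = 21L, tau = 1L, solid_threshold = 1 - 1e-3,
                              max_iterations = 3L, change_fraction_stop = 0.002,
                              phred_offset = 33L, epsilon = 0.01,
                              max_quadratic = 1000L, canonical = FALSE,
                              hammer_emulate = FALSE, no_expansion = FALSE,
                              bic_distinct = FALSE, trim_quality = NULL,
                              n_files = NULL, workdir = tempdir(), seed = 1L) {
  stopifnot(k >= tau + 1L, tau >= 1L,
            solid_threshold > 0, solid_threshold < 1,
            epsilon > 0, epsilon < 1,
            max_iterations >= 1L,
            change_fraction_stop >= 0, change_fraction_stop <= 1,
            phred_offset %in% c(33L, 64L))
  structure(
    list(k = as.integer(k), tau = as.integer(tau),
         solid_threshold = solid_threshold,
         max_iterations = as.integer(max_iterations),
         change_fraction_stop = change_fraction_stop,
         phred_offset = as.integer(phred_offset), epsilon = epsilon,
         max_quadratic = as.integer(max_quadratic), canonical = canonical,
         hammer_emulate = hammer_emulate, no_expansion = no_expansion,
         bic_distinct = bic_distinct, trim_quality = trim_quality,
         n_files = n_files, workdir = workdir, seed = as.integer(seed)),
    class = "correction_config")
}

#' Run one correction iteration
#'
#' Executes the six stages in order: k-mer statistics, Hamming components,
#' subclustering, solid selection, expansion, consensus correction.
#'
#' @param reads A read tibble.
#' @param config A [correction_config()].
#' @return List with `reads` (corrected) and `report` (one-row tibble of
#'   stage counters).
#' @export
run_iteration <- function(reads, config = correction_config()) {
  index <- if (is.null(config$n_files)) {
    collect_statistics(reads, config$k, config$canonical)
  } else {
    bucketed_count(reads, config$k, config$n_files, config$workdir,
                   config$canonical)
  }
  membership <- hamming_components(index, config$tau, config$max_quadratic)
  sc <- subcluster_components(index, membership,
                              hammer_emulate = config$hammer_emulate,
                              distinct = config$bic_distinct)
  solid <- select_solid(sc, index, config$solid_threshold)
  n_solid_before <- sum(solid$solid)
  if (!config$no_expansion) solid <- expand_solid(reads, solid, index)
  res <- correct_reads(reads, solid, index)
  n_changed <- sum(res$outcome$changed)
  report <- tibble(
    n_reads = nrow(reads),
    n_distinct_kmers = length(index$kmers),
    n_components = if (length(membership)) max(membership) else 0L,
    n_subclusters = nrow(sc$clusters),
    n_solid_before_expansion = n_solid_before,
    n_solid_after_expansion = sum(solid$solid),
    n_reads_changed = n_changed,
    n_positions_changed = sum(res$outcome$n_changed),
    fraction_reads_changed = if (nrow(reads)) n_changed / nrow(reads) else 0)
  list(reads = res$reads, report = report)
}

#' Run the full iterative correction pipeline
#'
#' Repeats [run_iteration()] until the fraction of reads changed drops
#' below `config$change_fraction_stop` or `config$max_iterations` is
#' reached; then applies optional quality trimming. The pipeline is fully
#' deterministic: identical input and configuration give byte-identical
#' output.
#'
#' @param reads A read tibble, e.g. from [read_fastq()].
#' @param config A [correction_config()].
#' @return A `correction_result`: list with `reads` (corrected),
#'   `iterations` (tibble, one row per iteration) and `config`.
#' @export
#' @examples
#' sim <- make_reads(make_genome(400, seed = 1), n_reads = 120,
#'                   read_len = 60, seed = 2)
#' res <- run_pipeline(sim$reads, correction_config(k = 15))
#' glance(res)
run_pipeline <- function(reads, config = correction_config()) {
  reports <- list()
  current <- reads
  for (it in seq_len(config$max_iterations)) {
    step <- run_iteration(current, config)
    current <- step$reads
    reports[[it]] <- mutate(step$report, iteration = it, .before = 1L)
    if (step$report$fraction_reads_changed < config$change_fraction_stop) break
  }
  if (!is.null(config$trim_quality)) {
    current <- trim_reads(current, config$trim_quality)
  }
  structure(list(reads = current, iterations = bind_rows(reports),
                 config = config),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  last <- x$iterations[nrow(x$iterations), ]
  cat(sprintf(
    "<correction_result> %d reads, %d iteration(s); last iteration changed %d reads (%.2f%%)\n",
    last$n_reads, nrow(x$iterations), last$n_reads_changed,
    100 * last$fraction_reads_changed))
  invisible(x)
}

#' Per-iteration counters of a correction run
#'
#' @param x A `correction_result`.
#' @param ... Unused.
#' @return The `iterations` tibble: distinct k-mers, components,
#'   subclusters, solid set sizes before/after expansion, reads and
#'   positions changed per iteration.
#' @export
tidy.correction_result <- function(x, ...) x$iterations

#' One-row summary of a correction run
#'
#' @param x A `correction_result`.
#' @param ... Unused.
#' @return Tibble with read count, iteration count, totals of changed
#'   reads/positions, and the final changed fraction.
#' @export
glance.correction_result <- function(x, ...) {
  tibble(n_reads = x$iterations$n_reads[1],
         n_iterations = nrow(x$iterations),
         total_reads_changed = sum(x$iterations$n_reads_changed),
         total_positions_changed = sum(x$iterations$n_positions_changed),
         final_fraction_changed =
           x$iterations$fraction_reads_changed[nrow(x$iterations)])
}

#' Plot per-iteration correction activity
#'
#' @param object A `correction_result`.
#' @param ... Unused.
#' @return A ggplot: reads changed per iteration.
#' @export
autoplot.correction_result <- function(object, ...) {
  ggplot2::ggplot(object$iterations,
                  ggplot2::aes(x = factor(.data$iteration),
                               y = .data$n_reads_changed)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "iteration", y = "reads changed",
                  title = "Correction activity per iteration") +
    ggplot2::theme_minimal()
}

#' Plot the k-mer multiplicity spectrum
#'
#' Histogram of distinct k-mer multiplicities on a log-count axis; under
#' amplification bias (MDA-like data) the spectrum has no clean separation
#' between error and genomic modes, which is why this package never applies
#' a coverage cutoff.
#'
#' @param index A `kmer_index`.
#' @return A ggplot.
#' @export
plot_kmer_spectrum <- function(index) {
  ggplot2::ggplot(tibble(count = index$count), ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey30") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "k-mer multiplicity", y = "distinct k-mers",
                  title = "k-mer multiplicity spectrum") +
    ggplot2::theme_minimal()
}
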