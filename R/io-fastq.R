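#' Convert Phred quality characters to error probabilities
#'
#' Decodes quality characters from a FASTQ quality string into per-base error
#' probabilities `10^(-Q/10)`, where `Q = ord(char) - offset`. Probabilities
#' are clamped strictly inside (0, 1) so that products over occurrences
#' (accumulated in log-space downstream) never collapse to 0 or 1; in
#' particular a Phred-0 character ('!' at offset 33) decodes to `clamp[2]`,
#' not to 1.
#'
#' @param qual Character vector of single quality characters, or a single
#'   quality string (which is split into characters).
#' @param offset Phred ASCII offset, 33 (Sanger/modern Illumina) or 64
#'   (legacy Illumina).
#' @param clamp Length-2 numeric, the closed interval probabilities are
#'   clamped into. Default `c(1e-10, 1 - 1e-10)`.
#' @return Numeric vector of error probabilities, one per character.
#' @export
#' @examples
#' phred_to_error_prob("5")        # Phred 20 -> 0.01
#' phred_to_error_prob("II5!")     # a whole quality string
phred_to_error_prob <- function(qual, offset = 33L, clamp = DEFAULT_CLAMP) {
  stopifnot(offset %in% c(33L, 64L), length(clamp) == 2L, clamp[1] < clamp[2])
  if (length(qual) == 1L && nchar(qual) != 1L) {
    qual <- strsplit(qual, "", fixed = TRUE)[[1]]
  }
  if (length(qual) == 0L) return(numeric(0))
  code <- utf8ToInt(paste(qual, collapse = ""))
  bad <- which(code < offset)
  if (length(bad) > 0L) {
    abort(sprintf(
      "malformed quality: character '%s' at position %d is below Phred offset %d",
      qual[bad[1]], bad[1], offset))
  }
  clamp01(10^(-(code - offset) / 10), clamp)
}

#' Construct a read table
#'
#' The read container used throughout the package: a tibble with one row per
#' read and columns `id`, `seq` (uppercase over A/C/G/T/N), `qual` (list
#' column of per-base error probabilities) and `raw_qual` (the original
#' quality string, preserved verbatim so corrected output keeps the input
#' quality characters).
#'
#' @param id Character vector of read identifiers.
#' @param seq Character vector of sequences; lowercase is uppercased and any
#'   base outside A/C/G/T is mapped to N.
#' @param raw_qual Character vector of Phred quality strings, same lengths
#'   as `seq`.
#' @param offset,clamp Passed to [phred_to_error_prob()].
#' @return A tibble of reads.
#' @export
read_table <- function(id, seq, raw_qual, offset = 33L, clamp = DEFAULT_CLAMP) {
  seq <- toupper(seq)
  seq <- gsub("[^ACGT]", "N", seq)
  if (any(nchar(seq) != nchar(raw_qual))) {
    i <- which(nchar(seq) != nchar(raw_qual))[1]
    abort(sprintf(
      "read '%s': sequence length %d does not match quality length %d",
      id[i], nchar(seq[i]), nchar(raw_qual[i])))
  }
  qual <- lapply(raw_qual, phred_to_error_prob, offset = offset, clamp = clamp)
  tibble(id = as.character(id), seq = seq, qual = qual, raw_qual = raw_qual)
}

#' Read a FASTQ file into a read table
#'
#' Parses 4-line-per-record FASTQ (gzip accepted transparently). Lowercase
#' bases are uppercased; bases outside A/C/G/T become N, so the downstream
#' "discard k-mers containing N" rule is the single masking mechanism.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @param offset Phred ASCII offset (33 or 64).
#' @param clamp Probability clamp, see [phred_to_error_prob()].
#' @return A read tibble, see [read_table()].
#' @export
read_fastq <- function(path, offset = 33L, clamp = DEFAULT_CLAMP) {
  con <- file(path, "r")  # file() decompresses gzip transparently
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    return(read_table(character(0), character(0), character(0)))
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("truncated FASTQ record starting at line %d of '%s'",
                  4L * (length(lines) %/% 4L) + 1L, path))
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  bad_hdr <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad_hdr) > 0L) {
    abort(sprintf("malformed FASTQ record at line %d of '%s'",
                  4L * (bad_hdr[1] - 1L) + 1L, path))
  }
  mism <- which(nchar(seq) != nchar(qual))
  if (length(mism) > 0L) {
    abort(sprintf(
      "FASTQ record at line %d of '%s': quality length %d != sequence length %d",
      4L * (mism[1] - 1L) + 1L, path, nchar(qual[mism[1]]), nchar(seq[mism[1]])))
  }
  read_table(sub("^@", "", hdr), seq, qual, offset = offset, clamp = clamp)
}

#' Write a read table to FASTQ
#'
#' Writes the original quality strings byte-for-byte, so that
#' `read_fastq(write_fastq(x))` round-trips ids, sequences and qualities
#' exactly; corrected bases keep the original quality character at their
#' position.
#'
#' @param reads A read tibble.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    rec <- rbind(paste0("@", reads$id), reads$seq, "+", reads$raw_qual)
    writeLines(as.vector(rec), con)
  }
  invisible(path)
}
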