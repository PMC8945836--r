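# Read-level quality control: the three raw-read filters (N fraction, low
# quality, adapter contamination) and library-level PCR-duplicate removal.
# All predicates are pure; pair handling drops a pair when either mate fails.

#' Construct a sequencing read
#'
#' @param id Read identifier.
#' @param sequence Base string over A/C/G/T/N.
#' @param qualities Integer phred scores (offset already removed), same length
#'   as `sequence`.
#' @param mate_id Optional mate identifier.
#' @return A list of class `seq_read`.
#' @export
seq_read <- function(id, sequence, qualities, mate_id = NULL) {
  sequence <- toupper(sequence)
  qualities <- as.integer(qualities)
  if (nchar(sequence) != length(qualities))
    abort_("sequence and qualities must have equal length")
  if (any(qualities < 0L)) abort_("phred qualities must be >= 0")
  structure(list(id = id, sequence = sequence, qualities = qualities,
                 mate_id = mate_id), class = "seq_read")
}

#' N-content filter
#'
#' Drop a read when 10% or more of its bases are unidentified (N). The 10%
#' boundary itself is dropped (inclusive comparator).
#'
#' @param read A [seq_read()].
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_n_fraction <- function(read) {
  n <- nchar(read$sequence)
  if (n == 0L) abort_("empty sequence")
  n_count <- n - nchar(gsub("N", "", read$sequence, fixed = TRUE))
  (n_count / n) < 0.10
}

#' Low-quality filter
#'
#' Drop a read when strictly more than 50% of bases have phred quality below
#' 5. Exactly half low-quality bases is kept (strict comparator).
#'
#' @inheritParams filter_n_fraction
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_low_quality <- function(read) {
  n <- length(read$qualities)
  if (n == 0L) abort_("empty sequence")
  (sum(read$qualities < 5L) / n) <= 0.50
}

#' Adapter-contamination filter
#'
#' Drop a read when some ungapped alignment of an adapter substring to the
#' read spans more than 10 nt with a mismatch fraction of at most 10%
#' (inclusive). All relative offsets of the adapter against the read are
#' scanned, including partial overhangs at both read ends, and within each
#' offset all contiguous sub-alignments longer than 10 nt are considered.
#'
#' @inheritParams filter_n_fraction
#' @param adapter Adapter sequence (nonempty).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_adapter <- function(read, adapter) {
  adapter <- toupper(adapter)
  la <- nchar(adapter)
  if (la == 0L) abort_("adapter must be nonempty")
  r <- strsplit(read$sequence, "", fixed = TRUE)[[1L]]
  a <- strsplit(adapter, "", fixed = TRUE)[[1L]]
  lr <- length(r)
  # offset d: adapter position j aligns to read position j + d
  for (d in seq.int(-la + 1L, lr - 1L)) {
    j_lo <- max(1L, 1L - d); j_hi <- min(la, lr - d)
    ov <- j_hi - j_lo + 1L
    if (ov <= 10L) next
    mism <- cumsum(c(0L, a[j_lo:j_hi] != r[(j_lo + d):(j_hi + d)]))
    # windows [i1, i2] within the overlap, length > 10
    for (len in 11L:ov) {
      ms <- mism[(len + 1L):(ov + 1L)] - mism[1L:(ov - len + 1L)]
      if (any(ms / len <= 0.10)) return(FALSE)
    }
  }
  TRUE
}

#' PCR-duplicate removal on read pairs
#'
#' Among pairs with an identical (sequence1, sequence2) combination only the
#' first occurrence in input order is retained; the output is a subsequence of
#' the input.
#'
#' @param pairs List of 2-element lists of [seq_read()] objects.
#' @return The deduplicated list of pairs.
#' @export
remove_duplicates <- function(pairs) {
  if (length(pairs) == 0L) return(pairs)
  key <- vapply(pairs, function(p) paste(p[[1L]]$sequence, p[[2L]]$sequence,
                                         sep = "\x01"), character(1))
  pairs[!duplicated(key)]
}

#' Apply all QC rules to paired reads
#'
#' A pair is dropped when either mate fails the N-content, low-quality or
#' adapter rule; PCR duplicates are then removed among the survivors.
#'
#' @param pairs List of read pairs.
#' @param adapter Adapter sequence.
#' @return List with `pairs` (survivors) and `drop_counts` (named integer
#'   vector: n_fraction, low_quality, adapter, duplicate — a pair counts once,
#'   under the first rule it fails).
#' @export
qc_pairs <- function(pairs, adapter) {
  counts <- c(n_fraction = 0L, low_quality = 0L, adapter = 0L, duplicate = 0L)
  keep <- logical(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (!filter_n_fraction(p[[1L]]) || !filter_n_fraction(p[[2L]])) {
      counts["n_fraction"] <- counts["n_fraction"] + 1L
    } else if (!filter_low_quality(p[[1L]]) || !filter_low_quality(p[[2L]])) {
      counts["low_quality"] <- counts["low_quality"] + 1L
    } else if (!filter_adapter(p[[1L]], adapter) ||
               !filter_adapter(p[[2L]], adapter)) {
      counts["adapter"] <- counts["adapter"] + 1L
    } else keep[i] <- TRUE
  }
  out <- remove_duplicates(pairs[keep])
  counts["duplicate"] <- sum(keep) - length(out)
  list(pairs = out, drop_counts = counts)
}

#' Read a FASTQ file into seq_read objects
#'
#' Phred offset 33; gzip input is supported by the underlying parser.
#'
#' @param path FASTQ file path.
#' @return List of [seq_read()] objects.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- as(Biostrings::PhredQuality(S4Vectors::mcols(s)$qualities),
          "IntegerList")
  lapply(seq_along(s), function(i)
    seq_read(names(s)[i], as.character(s[[i]]), as.integer(q[[i]])))
}

#' Write seq_read objects to FASTQ (phred offset 33)
#'
#' @param reads List of [seq_read()] objects.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(vapply(reads, `[[`, "", "sequence"))
  names(s) <- vapply(reads, `[[`, "", "id")
  q <- Biostrings::PhredQuality(vapply(reads, function(r)
    rawToChar(as.raw(r$qualities + 33L)), character(1)))
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  invisible(path)
}
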