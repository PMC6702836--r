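#' Read-QC parameters
#'
#' Quality trimming keeps, for each read, the longest contiguous window
#' containing at most `max_below` bases with Phred quality below
#' `phred_floor` (the dynamic-trim budget of "Phred floor 15, at most 5 bases
#' below"); reads whose best window is shorter than `min_len` are removed.
#' Dereplication collapses reads sharing an identical first `dup_prefix_len`
#' bases.
#'
#' @param phred_floor Phred quality floor (default 15).
#' @param max_below Maximum number of bases below the floor tolerated within
#'   the kept window (default 5).
#' @param min_len Minimum post-trim read length in bp (default 50).
#' @param dup_prefix_len Prefix length in bp used to detect artificial
#'   replicates (default 50).
#' @return A list of class `"qc_params"`.
#' @export
qc_params <- function(phred_floor = 15L, max_below = 5L, min_len = 50L,
                      dup_prefix_len = 50L) {
  stopifnot(phred_floor >= 0, max_below >= 0, min_len >= 1, dup_prefix_len >= 0)
  structure(list(phred_floor = as.integer(phred_floor),
                 max_below = as.integer(max_below),
                 min_len = as.integer(min_len),
                 dup_prefix_len = as.integer(dup_prefix_len)),
            class = "qc_params")
}

phred_values <- function(qual) utf8ToInt(qual) - 33L

# Longest contiguous window with at most max_below positions below the floor;
# two-pointer scan, leftmost window on ties. Returns c(start, end) or NULL.
best_quality_window <- function(phred, floor, max_below) {
  n <- length(phred)
  if (n == 0) return(NULL)
  below <- phred < floor
  best <- c(1L, 0L)  # empty
  left <- 1L
  bad <- 0L
  for (right in seq_len(n)) {
    bad <- bad + below[right]
    while (bad > max_below) {
      bad <- bad - below[left]
      left <- left + 1L
    }
    if (right - left > best[2] - best[1]) best <- c(left, right)
  }
  if (best[2] < best[1]) NULL else best
}

#' Quality-trim reads
#'
#' Trims each read to its longest contiguous window containing at most
#' `max_below` bases below the Phred floor (leftmost such window on ties) and
#' removes reads whose trimmed window is shorter than `min_len`. A read with
#' no more than `max_below` low-quality bases overall is kept untrimmed.
#' Idempotent on its own output.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual` (Phred+33).
#' @param params A [qc_params()].
#' @return A list with `kept` (trimmed reads data frame) and `removed`
#'   (count of discarded reads).
#' @export
qc_filter_reads <- function(reads, params = qc_params()) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) == 0) return(list(kept = reads, removed = 0L))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("quality string length differs from sequence length")
  keep <- logical(nrow(reads))
  seq_out <- character(nrow(reads))
  qual_out <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    w <- best_quality_window(phred_values(reads$qual[i]),
                             params$phred_floor, params$max_below)
    if (!is.null(w) && (w[2] - w[1] + 1L) >= params$min_len) {
      keep[i] <- TRUE
      seq_out[i] <- substr(reads$seq[i], w[1], w[2])
      qual_out[i] <- substr(reads$qual[i], w[1], w[2])
    }
  }
  kept <- data.frame(id = reads$id[keep], seq = seq_out[keep],
                     qual = qual_out[keep], stringsAsFactors = FALSE)
  list(kept = kept, removed = sum(!keep))
}

#' Remove artificial replicate reads
#'
#' Among reads sharing an identical first `dup_prefix_len` bases, only the
#' longest is kept (the first encountered on length ties); reads shorter than
#' the prefix length are compared on their full length.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param params A [qc_params()].
#' @return A list with `kept` (reads data frame, original order) and
#'   `removed` (count).
#' @export
dereplicate_reads <- function(reads, params = qc_params()) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) == 0) return(list(kept = reads, removed = 0L))
  key <- substr(reads$seq, 1, params$dup_prefix_len)
  len <- nchar(reads$seq)
  # stable: within a key, keep the longest; first encountered wins ties
  ord <- order(key, -len, seq_along(key), method = "radix")
  winner_rows <- ord[!duplicated(key[ord])]
  keep <- sort(winner_rows)
  kept <- reads[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = nrow(reads) - length(keep))
}

#' Summarize a read set
#'
#' Computes the submission/QC bookkeeping statistics: total base pairs, read
#' count, read-length mean and sample standard deviation, and per-read GC%
#' mean and sample standard deviation. GC% of a read is
#' `100 * (G + C) / (A + C + G + T)`; ambiguous bases are excluded from both
#' numerator and denominator. A single read (or an all-ambiguous read set)
#' reports standard deviations of 0; an empty read set reports all zeros.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @return A list of class `"qc_summary"` with `bp_count`, `seq_count`,
#'   `len_mean`, `len_sd`, `gc_mean`, `gc_sd`.
#' @export
summarize_reads <- function(reads) {
  zero_sd <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  if (nrow(reads) == 0)
    return(structure(list(bp_count = 0, seq_count = 0L, len_mean = 0,
                          len_sd = 0, gc_mean = 0, gc_sd = 0),
                     class = "qc_summary"))
  len <- nchar(reads$seq)
  base_counts <- function(s, chars) {
    sum(vapply(chars, function(ch)
      lengths(regmatches(s, gregexpr(ch, s, fixed = TRUE))), numeric(1)))
  }
  gc <- vapply(reads$seq, function(s) {
    up <- toupper(s)
    g_c <- base_counts(up, c("G", "C"))
    a_t <- base_counts(up, c("A", "T"))
    if (g_c + a_t == 0) NA_real_ else 100 * g_c / (g_c + a_t)
  }, numeric(1), USE.NAMES = FALSE)
  gc <- gc[!is.na(gc)]
  structure(list(bp_count = sum(len), seq_count = nrow(reads),
                 len_mean = mean(len), len_sd = zero_sd(len),
                 gc_mean = if (length(gc) == 0) 0 else mean(gc),
                 gc_sd = zero_sd(gc)),
            class = "qc_summary")
}

#' Run the full read-QC stage
#'
#' Quality trimming followed by dereplication, with before/after summaries --
#' the per-sample bookkeeping of a sequencing QC table. Screening reads
#' against a host reference genome is an upstream step that requires an
#' external reference and aligner; it is not performed here, and a message
#' records that it was skipped.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param params A [qc_params()].
#' @param host_screen Ignored placeholder; if not `NULL`, a message notes the
#'   screening step is not implemented.
#' @return A list with `kept`, `removed_quality`, `removed_duplicates`,
#'   `summary_before`, `summary_after`.
#' @export
run_read_qc <- function(reads, params = qc_params(), host_screen = NULL) {
  if (!is.null(host_screen))
    message("host-genome screening not implemented; step skipped")
  before <- summarize_reads(reads)
  qf <- qc_filter_reads(reads, params)
  dr <- dereplicate_reads(qf$kept, params)
  list(kept = dr$kept,
       removed_quality = qf$removed,
       removed_duplicates = dr$removed,
       summary_before = before,
       summary_after = summarize_reads(dr$kept))
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (Phred+33 qualities).
#' @return Data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # coercions drop the (empty) metadata columns; that warning is noise here
  suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    out <- data.frame(id = names(x), seq = as.character(x),
                      qual = as.character(Biostrings::quality(x)),
                      stringsAsFactors = FALSE, row.names = NULL)
  })
  out
}

#' Write a FASTQ file
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param path Destination path; standard 4-line FASTQ, Phred+33.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}
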