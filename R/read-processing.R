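# Read QC and spacer extraction from expanded-array amplicons: reads are
# kept if their mean Phred quality passes a threshold, CRISPR repeats are
# located by Hamming distance with a mismatch budget, and the segments
# between consecutive repeats are the candidate spacers (the leader-proximal
# one being the newly acquired spacer).

#' Extraction configuration
#'
#' @param repeat_seq the CRISPR repeat sequence.
#' @param max_repeat_mismatches mismatch budget for repeat identification
#'   (default 2).
#' @param spacer_length accepted spacer length (default 33).
#' @param min_quality mean-Phred threshold for read retention (default 20).
#' @return object of class `extraction_config`.
#' @export
extraction_config <- function(repeat_seq, max_repeat_mismatches = 2L,
                              spacer_length = 33L, min_quality = 20) {
  stopifnot(max_repeat_mismatches >= 0, spacer_length > 0, nchar(repeat_seq) > 0)
  structure(list(repeat_seq = toupper(repeat_seq),
                 max_repeat_mismatches = as.integer(max_repeat_mismatches),
                 spacer_length = as.integer(spacer_length),
                 min_quality = min_quality),
            class = "extraction_config")
}

#' Filter reads by mean Phred quality
#'
#' Retains reads whose mean per-base Phred score is at least `min_quality`;
#' input order is preserved.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (Phred+33), as
#'   returned by [read_fastq].
#' @param min_quality threshold (default 20).
#' @return the retained subset, same columns and order.
#' @export
quality_filter <- function(reads, min_quality = 20) {
  if (nrow(reads) == 0L) return(reads)
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad))
    stop("malformed record ", bad[1L], ": sequence/quality length mismatch")
  means <- vapply(reads$qual, function(q) mean(phred_to_int(q)), numeric(1L),
                  USE.NAMES = FALSE)
  reads[means >= min_quality, , drop = FALSE]
}

# Hamming mismatch count of `pattern` against every window of `seq`
# (linear, no wrap). Returns an integer vector over 0-based offsets.
hamming_profile <- function(seq, pattern) {
  n <- nchar(seq)
  m <- nchar(pattern)
  if (m > n) return(integer(0))
  s <- utf8ToInt(seq)
  p <- utf8ToInt(pattern)
  n_off <- n - m + 1L
  mm <- integer(n_off)
  # column-at-a-time over the pattern: m passes over n_off offsets
  off <- seq_len(n_off) - 1L
  for (j in seq_len(m)) mm <- mm + (s[off + j] != p[j])
  mm
}

#' Locate CRISPR repeats in a read
#'
#' Finds non-overlapping windows within Hamming distance `max_mm` of the
#' repeat, greedily left to right; overlapping candidates are resolved by
#' lowest mismatch count, ties by leftmost position.
#'
#' @param seq read sequence.
#' @param repeat_seq repeat to find.
#' @param max_mm mismatch budget.
#' @return data.frame with columns `start`, `end` (1-based, inclusive) and
#'   `mismatches`, ordered by position.
#' @export
locate_repeats <- function(seq, repeat_seq, max_mm = 2L) {
  hit <- repeat_starts(seq, repeat_seq, max_mm)
  data.frame(start = hit$start, end = hit$start + nchar(repeat_seq) - 1L,
             mismatches = hit$mm)
}

# Allocation-light core of locate_repeats (called once or twice per read).
repeat_starts <- function(seq, repeat_seq, max_mm) {
  m <- nchar(repeat_seq)
  mm <- hamming_profile(seq, repeat_seq)
  cand <- which(mm <= max_mm)  # 1-based starts
  out_start <- integer(0)
  out_mm <- integer(0)
  while (length(cand)) {
    first <- cand[1L]
    cluster <- cand[cand < first + m]
    best <- cluster[which.min(mm[cluster])]  # which.min = leftmost on ties
    out_start <- c(out_start, best)
    out_mm <- c(out_mm, mm[best])
    cand <- cand[cand >= best + m]
  }
  list(start = out_start, mm = out_mm)
}

#' Extract spacer candidates from one read
#'
#' Repeats are located in the read and in its reverse complement; the
#' orientation with more repeat hits is used (amplicon orientation is primer
#' determined but unknown). Segments strictly between consecutive repeats
#' are returned; only segments of exactly `spacer_length` survive, and the
#' leader-proximal (first) segment is flagged as the newly acquired spacer.
#'
#' @param seq read sequence (quality filtering is done beforehand).
#' @param cfg an [extraction_config].
#' @param rcseq the read's reverse complement, if already computed
#'   (recomputed otherwise; [extract_pool] precomputes it for the whole
#'   pool at once).
#' @return data.frame with columns `spacer` and `acquired` (logical); zero
#'   rows when fewer than two repeats are found.
#' @export
extract_spacers <- function(seq, cfg, rcseq = NULL) {
  if (is.null(rcseq)) rcseq <- revcomp(seq)
  res <- extract_segments(seq, rcseq, cfg)
  data.frame(spacer = res$segs, acquired = res$acquired)
}

# Core of extract_spacers without data.frame overhead.
extract_segments <- function(seq, rcseq, cfg) {
  m <- nchar(cfg$repeat_seq)
  fwd <- repeat_starts(seq, cfg$repeat_seq, cfg$max_repeat_mismatches)
  rev <- repeat_starts(rcseq, cfg$repeat_seq, cfg$max_repeat_mismatches)
  if (length(rev$start) > length(fwd$start)) {
    starts <- rev$start
    use <- rcseq
  } else {
    starts <- fwd$start
    use <- seq
  }
  k <- length(starts)
  if (k < 2L) return(list(segs = character(0), acquired = logical(0)))
  seg_start <- starts[-k] + m
  seg_end <- starts[-1L] - 1L
  segs <- substring(use, seg_start, seg_end)
  acquired <- seq_along(segs) == 1L
  keep <- (seg_end - seg_start + 1L) == cfg$spacer_length
  list(segs = segs[keep], acquired = acquired[keep])
}

#' Extract spacers from a pool of reads
#'
#' Applies [quality_filter] then [extract_spacers] to every read.
#'
#' @param reads data.frame `id`/`seq`/`qual`.
#' @param cfg an [extraction_config].
#' @param acquired_only keep only the leader-proximal acquired spacer of
#'   each read (default TRUE).
#' @return character vector of spacer sequences (one element per accepted
#'   segment).
#' @export
extract_pool <- function(reads, cfg, acquired_only = TRUE) {
  reads <- quality_filter(reads, cfg$min_quality)
  rcs <- revcomp(reads$seq)
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    sp <- extract_segments(reads$seq[i], rcs[i], cfg)
    out[[i]] <- if (acquired_only) sp$segs[sp$acquired] else sp$segs
  }
  unlist(out, use.names = FALSE)
}

#' Tally spacer sequences
#'
#' @param spacers character vector.
#' @return named integer vector of exact multiset counts (total preserved).
#' @export
tally_spacers <- function(spacers) {
  if (length(spacers) == 0L)
    return(structure(integer(0), names = character(0)))
  tab <- table(spacers)
  structure(as.integer(tab), names = names(tab))
}
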