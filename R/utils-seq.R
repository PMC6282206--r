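# Low-level sequence plumbing shared by all modules. Sequences are plain
# uppercase ACGT character strings; replicons are circular with 0-based
# coordinates (a feature's start is its first base; windows wrap mod L).

#' Reverse complement of DNA strings
#'
#' @param x character vector of ACGT strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA string with a given GC content
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1 - gc)/2. Uses the current RNG state.
#'
#' @param n length in bases.
#' @param gc GC fraction in \[0, 1\].
#' @return a single character string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Fetch `len` bases of a circular sequence starting at 0-based `start0`,
# on the plus strand (reading forward) or the minus strand (the minus-strand
# feature's first base sits at plus-coordinate start0 and reading proceeds
# toward decreasing plus coordinates; the returned string is 5'->3' on minus).
circ_fetch <- function(seq, start0, len, strand = "+") {
  L <- nchar(seq)
  stopifnot(L >= 1, len >= 0)
  if (strand == "+") {
    i <- (start0 + seq_len(len) - 1L) %% L
    paste(substring(seq, i + 1L, i + 1L), collapse = "")
  } else {
    i <- (start0 - (seq_len(len) - 1L)) %% L
    s <- paste(substring(seq, i + 1L, i + 1L), collapse = "")
    chartr("ACGT", "TGCA", s)
  }
}

# Vectorised plus-strand circular windows: all `len`-base windows starting at
# the 0-based positions in `starts0`. Returns a character vector.
circ_windows <- function(seq, starts0, len) {
  L <- nchar(seq)
  doubled <- paste0(seq, substr(seq, 1L, min(len - 1L, L)))
  substring(doubled, starts0 + 1L, starts0 + len)
}

# Overlapping occurrence count of a fixed pattern in each sequence.
count_pattern <- function(pattern, seqs) {
  if (length(seqs) == 0L) return(integer(0))
  Biostrings::vcountPattern(pattern, Biostrings::DNAStringSet(seqs))
}

# 0-based start positions (within the linear string) of overlapping
# occurrences of `pattern` in a single sequence.
pattern_starts0 <- function(pattern, seq) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq))
  BiocGenerics::start(m) - 1L
}

# Pooled overlapping k-mer occurrence counts over a set of sequences:
# named integer vector over all 4^k k-mers (zeros kept, lexicographic order).
kmer_counts <- function(seqs, k) {
  stopifnot(k >= 1)
  if (length(seqs) == 0L) stop("empty sequence set")
  m <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                            width = k)
  counts <- colSums(m)
  storage.mode(counts) <- "integer"
  counts
}

#' Read a 4-line FASTQ file
#'
#' @param path FASTQ file (uncompressed or gzipped; `gzfile` transparent).
#' @return data.frame with columns `id`, `seq`, `qual` (Phred+33 strings).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("malformed FASTQ '", path, "': ", n, " lines (not a multiple of 4)")
  idx <- seq(1L, n, by = 4L)
  ids <- lines[idx]
  bad <- which(substr(ids, 1L, 1L) != "@")
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in '", path,
         "': header does not start with '@'")
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in '", path,
         "': sequence and quality lengths differ")
  data.frame(id = sub("^@", "", ids), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

#' Write reads as 4-line FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  out <- character(4L * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$seq
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- reads$qual
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) stop("cannot write FASTQ '", path,
                                          "': ", conditionMessage(e)))
  invisible(path)
}

#' Read FASTA sequences as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Phred+33 helpers.
phred_to_int <- function(qual) utf8ToInt(qual) - 33L
int_to_phred <- function(q) intToUtf8(pmin(pmax(q, 0L), 93L) + 33L)
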