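# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths (and Biostrings, where the implementation
# relies on it) so that agreement is a real cross-check.

# E. coli type I-E style 29-nt CRISPR repeat (used as a fixture throughout).
REPEAT_SEQ <- "GAGTTCCCCGCGCCAGCGGGGATAAACCG"

# Independent reverse complement (chartr + character reversal).
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Independent circular window fetch: rotate the doubled string.
oracle_circ_window <- function(seq, start0, len) {
  big <- strrep(seq, ceiling((start0 + len) / nchar(seq)) + 1L)
  substr(big, start0 + 1L, start0 + len)
}

# Brute-force sliding Hamming scan: all 1-based offsets with <= max_mm
# mismatches (no overlap resolution).
oracle_hamming_hits <- function(seq, pattern, max_mm) {
  sv <- strsplit(seq, "")[[1L]]
  pv <- strsplit(pattern, "")[[1L]]
  m <- length(pv)
  n <- length(sv)
  if (m > n) return(integer(0))
  which(vapply(seq_len(n - m + 1L), function(o) {
    sum(sv[o:(o + m - 1L)] != pv) <= max_mm
  }, logical(1L)))
}

# Exhaustive two-sided Fisher exact p for a 2x2 table (a, b / c, d):
# enumerate the full hypergeometric support at fixed margins and sum the
# probabilities of tables at most as probable as the observed one (with
# the conventional 1e-7 relative tie tolerance).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1)
  p_obs <- logp[x == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# Sample odds ratio with Haldane +0.5 correction at zero cells.
oracle_or <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  else (a * d) / (b * c)
}

# Overlapping occurrence count of a pattern via regmatches-free scan.
oracle_count <- function(pattern, s) {
  m <- nchar(pattern)
  n <- nchar(s)
  if (n < m) return(0L)
  sum(vapply(seq_len(n - m + 1L),
             function(o) substr(s, o, o + m - 1L) == pattern, logical(1L)))
}

# A small standard simulated experiment used by several tests.
standard_sim <- function(seed = 1L, length = 3000L, n_reads = 2e4L,
                         replicates = 2L, model = acquisition_model(
                           plasmid_fraction = 1, seed = seed + 1000L)) {
  priming <- "ACCGTTAACCGGTTAACCGGTTAACCGGTTAAC"
  pl <- make_plasmid(length, 0.5, priming, priming_start = 100L,
                     priming_strand = "+", seed = seed)
  cat_full <- catalog_prespacers(pl, pam = NULL)
  rates <- assign_rates(cat_full, model)
  sim <- simulate_counts(rates, n_reads, model, replicates = replicates,
                         seed = seed + 2000L)
  list(plasmid = pl, catalog = cat_full, rates = rates, sim = sim,
       model = model)
}
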