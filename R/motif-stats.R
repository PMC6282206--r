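# Motif-avoidance statistics: k-mer odds ratios between hot and cold
# sequence sets by Fisher's exact test, 6-bp sliding-window AAG profiles
# with Poisson confidence bounds, regional AAG-vs-frequency correlations
# with Fisher z intervals, whole-spacer R^2, and genome-wide trinucleotide
# avoidance.

# Two-sided Fisher exact p and odds ratio for one 2x2 table
# (a = focal/set1, b = rest/set1, c = focal/set2, d = rest/set2).
# The sample OR gets the Haldane +0.5 correction when any cell is zero;
# the p-value comes from the uncorrected exact test.
fisher_2x2 <- function(a, b, c, d) {
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L))$p.value
  or <- if (any(c(a, b, c, d) == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  else (a * d) / (b * c)
  list(odds_ratio = or, p_value = p)
}

all_kmers <- function(k) {
  g <- do.call(expand.grid, c(rep(list(DNA_BASES), k),
                              stringsAsFactors = FALSE))
  sort(do.call(paste0, g))
}

# Occurrence counts per k-mer for a set: overlapping windows pooled across
# sequences ("overlap") or number of sequences containing the k-mer
# ("presence"). Returns list(counts, total) where total is the column margin.
kmer_set_counts <- function(seqs, k, mode) {
  if (mode == "overlap") {
    counts <- kmer_counts(seqs, k)
    list(counts = counts, total = sum(counts))
  } else {
    m <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                              width = k)
    counts <- colSums(m > 0)
    storage.mode(counts) <- "integer"
    # presence/absence: each sequence is one trial per k-mer
    list(counts = counts, total = length(seqs))
  }
}

#' k-mer odds ratios between hot and cold sequence sets
#'
#' For every k-mer, a 2x2 contingency table of (this k-mer vs all other
#' k-mer windows) x (hot vs cold) is built from pooled overlapping
#' occurrence counts, and the two-sided Fisher exact p-value and odds ratio
#' (Haldane +0.5 correction when a cell is zero) are computed. A Bonferroni
#' column over the 4^k tests is added for convenience; no correction is
#' applied to `p_value` itself.
#'
#' @param hot_seqs,cold_seqs character vectors of equal-length sequences.
#' @param k k-mer size (1, 2 or 3 in typical use).
#' @param mode `"overlap"` (pooled overlapping occurrences, default) or
#'   `"presence"` (per-sequence presence/absence).
#' @return data.frame with columns `kmer`, `count_hot`, `other_hot`,
#'   `count_cold`, `other_cold`, `odds_ratio`, `p_value`, `p_bonferroni`,
#'   one row per k-mer in lexicographic order.
#' @export
kmer_odds_ratios <- function(hot_seqs, cold_seqs, k = 3L,
                             mode = c("overlap", "presence")) {
  mode <- match.arg(mode)
  if (length(hot_seqs) == 0L || length(cold_seqs) == 0L)
    stop("hot and cold sets must both be nonempty")
  if (k > min(nchar(c(hot_seqs, cold_seqs))))
    stop("k exceeds sequence length")
  h <- kmer_set_counts(hot_seqs, k, mode)
  c_ <- kmer_set_counts(cold_seqs, k, mode)
  kmers <- all_kmers(k)
  out <- data.frame(kmer = kmers,
                    count_hot = as.integer(h$counts[kmers]),
                    other_hot = as.integer(h$total - h$counts[kmers]),
                    count_cold = as.integer(c_$counts[kmers]),
                    other_cold = as.integer(c_$total - c_$counts[kmers]))
  stats_list <- mapply(fisher_2x2, out$count_hot, out$other_hot,
                       out$count_cold, out$other_cold, SIMPLIFY = FALSE)
  out$odds_ratio <- vapply(stats_list, `[[`, numeric(1L), "odds_ratio")
  out$p_value <- vapply(stats_list, `[[`, numeric(1L), "p_value")
  out$p_bonferroni <- pmin(1, out$p_value * length(kmers))
  rownames(out) <- NULL
  out
}

#' k-mer odds ratios on prespacer flanks
#'
#' Runs [kmer_odds_ratios] on the 33-bp flanking windows (upstream of the
#' PAM or downstream of the prespacer) of hot vs cold spacers.
#'
#' @param hits annotated, categorized spacer table carrying `category`,
#'   `upstream_flank` and `downstream_flank` columns.
#' @param side `"upstream"` or `"downstream"`.
#' @param k k-mer size.
#' @param mode see [kmer_odds_ratios].
#' @return as [kmer_odds_ratios].
#' @export
flank_odds_ratios <- function(hits, side = c("upstream", "downstream"),
                              k = 3L, mode = c("overlap", "presence")) {
  side <- match.arg(side)
  col <- paste0(side, "_flank")
  stopifnot(col %in% names(hits), "category" %in% names(hits))
  kmer_odds_ratios(hits[[col]][hits$category == "hot"],
                   hits[[col]][hits$category == "cold"], k = k,
                   mode = match.arg(mode))
}

# Mean per-sequence count of AAG occurrences fully inside each sliding
# window: mean[w] = (# AAG starts in [w, w + window - 3]) / n_seqs.
window_aag_means <- function(seqs, window, pattern = "AAG") {
  L <- nchar(seqs[1L])
  stopifnot(all(nchar(seqs) == L))
  if (window > L) stop("window exceeds sequence length")
  starts <- unlist(lapply(seqs, function(s) pattern_starts0(pattern, s))) + 1L
  per_pos <- tabulate(starts, nbins = L)
  n_win <- L - window + 1L
  span <- window - nchar(pattern)
  vapply(seq_len(n_win), function(w)
    sum(per_pos[w:min(w + span, L)]) / length(seqs), numeric(1L))
}

# Axis where +1 is the G of the AAG PAM: PAM occupies -1, 0, +1; prespacer
# base i maps to i + 1; the upstream flank's 3'-most base abuts the PAM and
# the downstream flank starts right after prespacer base 33.
frame_axis_offset <- function(frame) {
  switch(frame, prespacer = 1, upstream_flank = -35, downstream_flank = 34)
}

#' Sliding-window AAG profile of hot vs cold sequences
#'
#' A `window`-bp window slides across the 33-bp frame; AAG occurrences
#' fully inside the window are counted per sequence and averaged within the
#' hot and cold sets (nu_h, nu_c). The difference nu_h - nu_c is reported
#' with a Poisson-based standard deviation sqrt(nu_h + nu_c) and a 95%
#' confidence half-width of 1.96 sd.
#'
#' @param hot_seqs,cold_seqs character vectors of 33-nt sequences (the
#'   prespacers themselves or their 33-bp flanks, per `frame`).
#' @param window window length (default 6).
#' @param frame `"prespacer"`, `"upstream_flank"` or `"downstream_flank"`;
#'   selects the coordinate axis where +1 is the G of the AAG PAM.
#' @return data.frame with one row per window start (28 rows for a 33-bp
#'   frame and 6-bp window): `window_start` (frame coordinates 1..28),
#'   `center` (PAM-G axis), `mean_hot_aag`, `mean_cold_aag`, `diff`, `sd`,
#'   `ci95_halfwidth`.
#' @export
sliding_window_profile <- function(hot_seqs, cold_seqs, window = 6L,
                                   frame = c("prespacer", "upstream_flank",
                                             "downstream_flank")) {
  frame <- match.arg(frame)
  stopifnot(length(hot_seqs) > 0, length(cold_seqs) > 0)
  nu_h <- window_aag_means(hot_seqs, window)
  nu_c <- window_aag_means(cold_seqs, window)
  w <- seq_along(nu_h)
  off <- frame_axis_offset(frame)
  data.frame(window_start = w,
             center = (w + off) + (window - 1) / 2,
             mean_hot_aag = nu_h, mean_cold_aag = nu_c,
             diff = nu_h - nu_c, sd = sqrt(nu_h + nu_c),
             ci95_halfwidth = 1.96 * sqrt(nu_h + nu_c))
}

# Pearson r with Fisher z 95% CI and two-sided p (SE = 1/sqrt(n - 3)).
pearson_fisher_z <- function(x, y) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                p_value = NA_real_, n = n))
  }
  r <- as.numeric(stats::cor(x, y))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  list(r = r, ci_lo = tanh(z - 1.96 * se), ci_hi = tanh(z + 1.96 * se),
       p_value = 2 * stats::pnorm(-abs(z) / se), n = n)
}

#' Regional AAG-count vs log-frequency correlations
#'
#' Prespacers are split into three nonoverlapping 11-bp regions (upstream
#' 1-11, middle 12-22, downstream 23-33; an AAG belongs to the region of
#' its first base). For each region, the Pearson correlation between
#' per-prespacer AAG counts and log spacer frequency is reported with a
#' 95% CI and p-value via the Fisher z transformation.
#'
#' @param seqs 33-nt prespacer sequences.
#' @param log_freq matching log10 sampling frequencies.
#' @return data.frame with columns `region`, `r`, `ci_lo`, `ci_hi`,
#'   `p_value`, `n`.
#' @export
regional_correlations <- function(seqs, log_freq) {
  stopifnot(length(seqs) == length(log_freq), length(seqs) >= 3)
  counts <- aag_region_counts(seqs)
  regions <- c("upstream", "middle", "downstream")
  rows <- lapply(1:3, function(j) {
    st <- pearson_fisher_z(counts[, j], log_freq)
    data.frame(region = regions[j], r = st$r, ci_lo = st$ci_lo,
               ci_hi = st$ci_hi, p_value = st$p_value, n = st$n)
  })
  do.call(rbind, rows)
}

#' Fraction of spacer-frequency variability explained by internal AAGs
#'
#' Pearson correlation between whole-prespacer AAG counts and log spacer
#' frequency, and its square (the coefficient of determination of the
#' linear fit).
#'
#' @param seqs 33-nt prespacer sequences.
#' @param log_freq matching log10 sampling frequencies.
#' @return list with `r`, `r_squared`, `n` (both `NA` with a warning on
#'   zero variance).
#' @export
variability_explained <- function(seqs, log_freq) {
  stopifnot(length(seqs) == length(log_freq), length(seqs) >= 3)
  counts <- count_pattern("AAG", seqs)
  if (stats::sd(counts) == 0 || stats::sd(log_freq) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_, n = length(seqs)))
  }
  r <- as.numeric(stats::cor(counts, log_freq))
  list(r = r, r_squared = r^2, n = length(seqs))
}

#' Trinucleotide avoidance in spacers vs genome-wide frequency
#'
#' For every k-mer, a 2x2 table of (this k-mer vs all other k-mer windows)
#' x (spacer set vs genome) is built; genome windows are counted on both
#' strands by default (spacers derive from either strand).
#'
#' @param spacers character vector of spacer sequences.
#' @param genome named character vector of genome sequences (or a single
#'   string), e.g. from [read_fasta].
#' @param k k-mer size (default 3).
#' @param both_strands count genome windows on both strands (default TRUE).
#' @return as [kmer_odds_ratios], with `count_hot`/`count_cold` columns
#'   named `count_spacers`/`count_genome`.
#' @export
genome_avoidance <- function(spacers, genome, k = 3L, both_strands = TRUE) {
  if (length(genome) == 0L || all(nchar(genome) == 0L))
    stop("genome is empty")
  gseqs <- unname(as.character(genome))
  if (both_strands) gseqs <- c(gseqs, revcomp(gseqs))
  out <- kmer_odds_ratios(spacers, gseqs, k = k, mode = "overlap")
  names(out)[names(out) == "count_hot"] <- "count_spacers"
  names(out)[names(out) == "other_hot"] <- "other_spacers"
  names(out)[names(out) == "count_cold"] <- "count_genome"
  names(out)[names(out) == "other_cold"] <- "other_genome"
  out
}
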