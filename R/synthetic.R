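# Seeded simulator of a primed-adaptation experiment: circular plasmids with a
# planted priming protospacer, prespacer catalogs, per-prespacer acquisition
# rates with position-dependent internal-AAG penalties, multinomial read
# counts with strand/PAM/replicon biases, and FASTQ amplicon reads of the
# expanded CRISPR array.

#' Construct a circular plasmid model
#'
#' Wraps an existing sequence together with the location and orientation of
#' its priming protospacer. Coordinates are 0-based and circular; a feature's
#' start is its first base on its own strand.
#'
#' @param name replicon name.
#' @param sequence uppercase ACGT string (circular).
#' @param priming_start 0-based position of the protospacer's first base.
#' @param priming_strand `"+"` or `"-"`.
#' @param priming_seq the 33-nt protospacer sequence (5'->3' on its strand).
#' @return an object of class `plasmid_model`.
#' @export
plasmid_model <- function(name, sequence, priming_start, priming_strand,
                          priming_seq) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  stopifnot(priming_strand %in% c("+", "-"),
            priming_start >= 0, priming_start < L)
  if (!grepl("^[ACGT]+$", sequence)) stop("sequence must be ACGT only")
  planted <- circ_fetch(sequence, priming_start, nchar(priming_seq),
                        priming_strand)
  if (planted != priming_seq)
    stop("priming_seq does not occur at (priming_start, priming_strand)")
  structure(list(name = name, sequence = sequence, length = L,
                 priming_start = as.integer(priming_start),
                 priming_strand = priming_strand, priming_seq = priming_seq),
            class = "plasmid_model")
}

#' @export
print.plasmid_model <- function(x, ...) {
  cat("Circular plasmid '", x$name, "': ", x$length, " bp; priming protospacer at ",
      x$priming_start, " (", x$priming_strand, " strand)\n", sep = "")
  invisible(x)
}

#' Generate a random circular plasmid with a planted priming protospacer
#'
#' @param length plasmid length in bases (>= 200).
#' @param gc GC fraction of the random backbone.
#' @param priming_seq 33-nt ACGT protospacer to plant.
#' @param priming_start 0-based position of the protospacer's first base.
#' @param priming_strand `"+"` or `"-"`.
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @param name replicon name.
#' @return a [plasmid_model].
#' @export
make_plasmid <- function(length, gc = 0.5, priming_seq,
                         priming_start = 100L, priming_strand = "+",
                         seed = 1L, name = "plasmid") {
  if (length < 200)
    stop("plasmid length ", length,
         " too small to host a protospacer plus flanks (need >= 200)")
  if (!grepl("^[ACGT]{33}$", priming_seq))
    stop("priming_seq must be 33 ACGT bases")
  stopifnot(priming_start >= 0, priming_start < length)
  set.seed(seed)
  seq <- random_dna(length, gc)
  # plant on the plus-strand footprint (read through the origin if it wraps)
  if (priming_strand == "+") {
    pos0 <- (priming_start + 0:32) %% length
    chars <- strsplit(priming_seq, "")[[1L]]
  } else {
    pos0 <- (priming_start - 32 + 0:32) %% length
    chars <- strsplit(revcomp(priming_seq), "")[[1L]]
  }
  sv <- strsplit(seq, "")[[1L]]
  sv[pos0 + 1L] <- chars
  plasmid_model(name, paste(sv, collapse = ""), priming_start,
                priming_strand, priming_seq)
}

# AAG occurrence counts by prespacer region (1-based start positions 1-11,
# 12-22, 23-33; an occurrence belongs to the region of its first base).
aag_region_counts <- function(seqs) {
  if (length(seqs) == 0L)
    return(matrix(integer(0), 0L, 3L,
                  dimnames = list(NULL, c("aag_r1", "aag_r2", "aag_r3"))))
  r1 <- count_pattern("AAG", substring(seqs, 1L, 13L))
  r2 <- count_pattern("AAG", substring(seqs, 12L, 24L))
  r3 <- count_pattern("AAG", substring(seqs, 23L, 33L))
  cbind(aag_r1 = r1, aag_r2 = r2, aag_r3 = r3)
}

#' Catalog prespacers on a circular plasmid
#'
#' Enumerates every 33-nt window on both strands whose 3 immediately 5'
#' bases (on the window's own strand) match `pam`; with `pam = NULL` all
#' 2L windows are returned. Coordinates wrap across the origin.
#'
#' @param plasmid a [plasmid_model].
#' @param pam 3-nt ACGT string, or `NULL` for all windows.
#' @param spacer_length prespacer length (default 33).
#' @return data.frame (class `prespacer_catalog`) with columns `replicon`,
#'   `start`, `strand`, `seq`, `pam`, `aag_r1`, `aag_r2`, `aag_r3`, sorted by
#'   (start, strand) with `"+"` first. The plasmid's priming strand and name
#'   are kept as attributes for downstream strand classification.
#' @export
catalog_prespacers <- function(plasmid, pam = "AAG", spacer_length = 33L) {
  stopifnot(inherits(plasmid, "plasmid_model"))
  if (!is.null(pam) && !grepl("^[ACGT]{3}$", pam))
    stop("pam must be 3 ACGT bases")
  L <- plasmid$length
  s <- plasmid$sequence
  starts <- 0:(L - 1L)
  plus_seq <- circ_windows(s, starts, spacer_length)
  plus_pam <- circ_windows(s, (starts - 3L) %% L, 3L)
  # minus-strand window with start s0 occupies plus coords (s0-32)..s0;
  # its PAM occupies plus coords (s0+1)..(s0+3)
  minus_seq <- revcomp(circ_windows(s, (starts - spacer_length + 1L) %% L,
                                    spacer_length))
  minus_pam <- revcomp(circ_windows(s, (starts + 1L) %% L, 3L))
  cat_df <- data.frame(
    replicon = plasmid$name,
    start = rep(starts, 2L),
    strand = rep(c("+", "-"), each = L),
    seq = c(plus_seq, minus_seq),
    pam = c(plus_pam, minus_pam),
    stringsAsFactors = FALSE)
  if (!is.null(pam)) cat_df <- cat_df[cat_df$pam == pam, , drop = FALSE]
  ord <- order(cat_df$start, match(cat_df$strand, c("+", "-")))
  cat_df <- cat_df[ord, , drop = FALSE]
  rownames(cat_df) <- NULL
  cat_df <- cbind(cat_df, aag_region_counts(cat_df$seq))
  attr(cat_df, "priming_strand") <- plasmid$priming_strand
  attr(cat_df, "replicon") <- plasmid$name
  class(cat_df) <- c("prespacer_catalog", "data.frame")
  cat_df
}

#' Acquisition model parameters
#'
#' Generative parameters of the simulated primed-adaptation experiment.
#' Per-prespacer log acquisition rates are a lognormal baseline minus a
#' penalty per internal AAG, position-dependent over three 11-bp prespacer
#' regions. Defaults reflect a typical primed-adaptation experiment: a
#' lognormal baseline spread of 1.5 nat (frequencies at fixed AAG count
#' spanning roughly three orders of magnitude, with internal AAGs explaining
#' a quarter to a third of log-frequency variance),
#' 86.35% of plasmid reads from the nontarget strand, 98.4% from AAG-PAM
#' prespacers, 99.7% from the plasmid, and region penalties giving a >10-fold
#' seed-region effect and 2-3-fold middle/end effects.
#'
#' @param baseline_log_rate_sd sd of the per-prespacer lognormal baseline
#'   (natural-log units).
#' @param beta_region nonnegative length-3 penalties (nat per internal AAG)
#'   for prespacer regions 1-11, 12-22, 23-33.
#' @param strand_bias fraction of plasmid reads from the nontarget strand.
#' @param pam_fidelity fraction of reads from AAG-PAM prespacers.
#' @param plasmid_fraction fraction of reads from the plasmid (vs host).
#' @param replicate_noise_sd sd of per-replicate lognormal rate jitter.
#' @param seed integer seed used by [assign_rates].
#' @return an object of class `acquisition_model`.
#' @export
acquisition_model <- function(baseline_log_rate_sd = 1.5,
                              beta_region = c(2.3, 0.7, 0.7),
                              strand_bias = 0.8635,
                              pam_fidelity = 0.984,
                              plasmid_fraction = 0.997,
                              replicate_noise_sd = 0.3,
                              seed = 1L) {
  stopifnot(length(beta_region) == 3L, all(beta_region >= 0),
            baseline_log_rate_sd >= 0, replicate_noise_sd >= 0)
  for (f in c(strand_bias, pam_fidelity, plasmid_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  structure(list(baseline_log_rate_sd = baseline_log_rate_sd,
                 beta_region = as.numeric(beta_region),
                 strand_bias = strand_bias, pam_fidelity = pam_fidelity,
                 plasmid_fraction = plasmid_fraction,
                 replicate_noise_sd = replicate_noise_sd,
                 seed = as.integer(seed)),
            class = "acquisition_model")
}

#' @export
print.acquisition_model <- function(x, ...) {
  cat("Acquisition model: baseline sd", x$baseline_log_rate_sd,
      "| AAG penalties", paste(x$beta_region, collapse = "/"),
      "| strand bias", x$strand_bias, "| PAM fidelity", x$pam_fidelity,
      "| plasmid fraction", x$plasmid_fraction, "\n")
  invisible(x)
}

#' Assign acquisition rates to a prespacer catalog
#'
#' log rate = N(0, baseline_log_rate_sd) - sum_r beta_region\[r\] * (internal
#' AAG count in region r). The lognormal baseline and applied penalty are
#' returned alongside the rate as ground truth for recovery tests.
#'
#' @param catalog a `prespacer_catalog`.
#' @param model an [acquisition_model]; `model$seed` makes the draw
#'   deterministic.
#' @return the catalog with added columns `baseline`, `penalty`, `log_rate`,
#'   `rate` (all natural-log scale except `rate`).
#' @export
assign_rates <- function(catalog, model) {
  stopifnot(inherits(model, "acquisition_model"), nrow(catalog) > 0)
  set.seed(model$seed)
  baseline <- rnorm(nrow(catalog), 0, model$baseline_log_rate_sd)
  penalty <- as.numeric(as.matrix(catalog[, c("aag_r1", "aag_r2", "aag_r3")]) %*%
                          model$beta_region)
  catalog$baseline <- baseline
  catalog$penalty <- penalty
  catalog$log_rate <- baseline - penalty
  catalog$rate <- exp(catalog$log_rate)
  catalog
}

# Multinomial draw of `n` reads over rows of a stratum, proportional to w.
draw_stratum <- function(n, w) {
  if (n == 0L) return(integer(length(w)))
  if (length(w) == 0L) stop("cannot draw reads: stratum catalog is empty")
  as.integer(rmultinom(1L, n, w))
}

#' Simulate per-replicate spacer read counts
#'
#' Reads are partitioned per replicate: plasmid vs host by
#' `plasmid_fraction`; plasmid reads by strand (`strand_bias` -> the
#' nontarget strand, i.e. the priming protospacer's strand); within each
#' strand by `pam_fidelity` (AAG vs other PAM). Nontarget AAG reads follow a
#' multinomial over the catalog's rates (with per-replicate lognormal
#' jitter); target-strand and non-AAG reads are drawn uniformly from the
#' complementary catalogs.
#'
#' @param rates a full-catalog output of [assign_rates] (both strands, all
#'   PAMs, of one plasmid).
#' @param n_spacer_reads reads per replicate.
#' @param model an [acquisition_model].
#' @param replicates number of replicates.
#' @param seed RNG seed for the draws.
#' @param host_catalog optional `prespacer_catalog` of a host replicon;
#'   required when `plasmid_fraction < 1`.
#' @param consensus_pam PAM consensus (default `"AAG"`).
#' @return data.frame: catalog columns plus `nontarget` flag and count
#'   columns `rep1..repK` (each summing to `n_spacer_reads`).
#' @export
simulate_counts <- function(rates, n_spacer_reads, model, replicates = 2L,
                            seed = 1L, host_catalog = NULL,
                            consensus_pam = "AAG") {
  stopifnot(inherits(model, "acquisition_model"), n_spacer_reads > 0,
            replicates >= 1, "rate" %in% names(rates))
  priming_strand <- attr(rates, "priming_strand")
  nontarget <- rates$strand == priming_strand
  is_aag <- rates$pam == consensus_pam
  strata <- list(nt_aag = which(nontarget & is_aag),
                 nt_non = which(nontarget & !is_aag),
                 t_aag = which(!nontarget & is_aag),
                 t_non = which(!nontarget & !is_aag))
  if (model$plasmid_fraction < 1 && is.null(host_catalog))
    stop("plasmid_fraction < 1 but no host catalog supplied (missing category: host)")
  if (model$strand_bias < 1 &&
      (length(strata$t_aag) + length(strata$t_non)) == 0L)
    stop("strand_bias < 1 but catalog has no target-strand prespacers (missing category: target strand)")
  if (model$pam_fidelity < 1 &&
      (length(strata$nt_non) + length(strata$t_non)) == 0L)
    stop("pam_fidelity < 1 but catalog has no non-", consensus_pam,
         "-PAM prespacers (missing category: non-consensus PAM)")
  n_host_rows <- if (is.null(host_catalog)) 0L else nrow(host_catalog)
  set.seed(seed)
  counts <- matrix(0L, nrow(rates) + n_host_rows, replicates,
                   dimnames = list(NULL, paste0("rep", seq_len(replicates))))
  for (r in seq_len(replicates)) {
    n_pl <- rbinom(1L, n_spacer_reads, model$plasmid_fraction)
    n_host <- n_spacer_reads - n_pl
    n_nt <- rbinom(1L, n_pl, model$strand_bias)
    n_t <- n_pl - n_nt
    n_nt_aag <- rbinom(1L, n_nt, model$pam_fidelity)
    n_t_aag <- rbinom(1L, n_t, model$pam_fidelity)
    w <- rates$rate[strata$nt_aag] *
      exp(rnorm(length(strata$nt_aag), 0, model$replicate_noise_sd))
    counts[strata$nt_aag, r] <- counts[strata$nt_aag, r] +
      draw_stratum(n_nt_aag, w)
    counts[strata$nt_non, r] <- counts[strata$nt_non, r] +
      draw_stratum(n_nt - n_nt_aag, rep(1, length(strata$nt_non)))
    counts[strata$t_aag, r] <- counts[strata$t_aag, r] +
      draw_stratum(n_t_aag, rep(1, length(strata$t_aag)))
    counts[strata$t_non, r] <- counts[strata$t_non, r] +
      draw_stratum(n_t - n_t_aag, rep(1, length(strata$t_non)))
    if (n_host > 0L) {
      idx <- nrow(rates) + seq_len(n_host_rows)
      counts[idx, r] <- counts[idx, r] +
        draw_stratum(n_host, rep(1, n_host_rows))
    }
  }
  keep <- c("replicon", "start", "strand", "seq", "pam",
            "aag_r1", "aag_r2", "aag_r3")
  out <- rbind(as.data.frame(rates)[, keep, drop = FALSE],
               if (n_host_rows)
                 as.data.frame(host_catalog)[, keep, drop = FALSE])
  out$nontarget <- c(nontarget, rep(FALSE, n_host_rows))
  out <- cbind(out, as.data.frame(counts))
  rownames(out) <- NULL
  attr(out, "priming_strand") <- priming_strand
  attr(out, "replicon") <- attr(rates, "replicon")
  out
}

#' CRISPR array amplicon template
#'
#' Layout of a simulated expanded-array amplicon read:
#' pad5 + leader + repeat + NEWSPACER + repeat + resident spacer + repeat +
#' pad3. The repeat must be >= 20 nt so 2-mismatch repeat identification is
#' unambiguous against random flanks.
#'
#' @param leader,repeat_seq,resident_spacer,pad5,pad3 ACGT strings;
#'   `resident_spacer` must be 33 nt.
#' @return object of class `array_template`.
#' @export
array_template <- function(leader, repeat_seq, resident_spacer,
                           pad5 = "", pad3 = "") {
  if (nchar(repeat_seq) < 20)
    stop("repeat must be >= 20 nt for unambiguous 2-mismatch identification")
  if (nchar(resident_spacer) != 33)
    stop("resident_spacer must be 33 nt")
  structure(list(leader = leader, repeat_seq = repeat_seq,
                 resident_spacer = resident_spacer,
                 pad5 = pad5, pad3 = pad3),
            class = "array_template")
}

# Apply per-base substitution errors (vectorised over equal-length reads).
apply_substitutions <- function(seqs, per_base_error) {
  if (per_base_error <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1L])
  n_err <- rbinom(length(seqs), L, per_base_error)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(L, n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seqs
}

# Quality strings ~ round(Normal(qual_mean, 3)) clipped to [2, 40].
sample_quals <- function(n_reads, read_len, qual_mean) {
  q <- pmin(pmax(round(rnorm(n_reads * read_len, qual_mean, 3)), 2L), 40L)
  m <- matrix(q, nrow = n_reads)
  vapply(seq_len(n_reads), function(i) int_to_phred(m[i, ]), character(1L))
}

#' Write expanded-array amplicon reads as FASTQ
#'
#' Emits one read per counted spacer with the [array_template] layout,
#' independent per-base substitution errors, and Phred qualities sampled
#' around `qual_mean`. Byte-identical output for identical seeds.
#'
#' @param counts named integer vector (names are 33-nt spacer sequences) or
#'   data.frame with columns `seq` and `count`.
#' @param template an [array_template].
#' @param per_base_error substitution probability per base.
#' @param qual_mean mean Phred quality.
#' @param out output FASTQ path.
#' @param seed RNG seed.
#' @return `out`, invisibly.
#' @export
write_array_fastq <- function(counts, template, per_base_error = 0.001,
                              qual_mean = 30, out, seed = 1L) {
  stopifnot(inherits(template, "array_template"))
  if (is.data.frame(counts)) {
    spacers <- counts$seq
    k <- counts$count
  } else {
    spacers <- names(counts)
    k <- as.integer(counts)
  }
  stopifnot(length(spacers) == length(k), all(k >= 0))
  set.seed(seed)
  reads <- rep(paste0(template$pad5, template$leader, template$repeat_seq,
                      spacers, template$repeat_seq, template$resident_spacer,
                      template$repeat_seq, template$pad3), k)
  reads <- apply_substitutions(reads, per_base_error)
  n <- length(reads)
  quals <- if (n > 0L) sample_quals(n, nchar(reads[1L]), qual_mean)
           else character(0)
  write_fastq(data.frame(id = sprintf("sim_%d", seq_len(n)),
                         seq = reads, qual = quals,
                         stringsAsFactors = FALSE), out)
  invisible(out)
}

#' Simulate a randomized-trinucleotide prespacer library
#'
#' Emulates the plasmid pool of a library experiment: `n_clones` plasmid
#' clones carry independent uniform-random trinucleotides at
#' `randomized_window` of the reference prespacer embedded in
#' `template_region`; `depth` amplicon reads sample the clones uniformly.
#'
#' @param template_region ACGT string containing the 33-nt reference
#'   prespacer.
#' @param prespacer_offset 1-based start of the prespacer in
#'   `template_region`.
#' @param randomized_window 1-based contiguous trinucleotide positions within
#'   1..33 (e.g. `2:4`).
#' @param n_clones number of plasmid clones pooled.
#' @param depth number of reads.
#' @param seed RNG seed.
#' @param per_base_error substitution error probability per base.
#' @param qual_mean mean Phred quality.
#' @param out optional FASTQ path; written when non-`NULL`.
#' @return list with `reads` (data.frame id/seq/qual), `truth` (named
#'   fractions over all 64 variants, summing to 1), and `path`.
#' @export
simulate_library <- function(template_region, prespacer_offset,
                             randomized_window, n_clones = 2000L,
                             depth = 10000L, seed = 1L,
                             per_base_error = 0, qual_mean = 30,
                             out = NULL) {
  randomized_window <- as.integer(randomized_window)
  if (length(randomized_window) != 3L ||
      any(diff(randomized_window) != 1L) ||
      randomized_window[1L] < 1L || randomized_window[3L] > 33L)
    stop("randomized_window must be a contiguous triple within 1..33")
  stopifnot(n_clones >= 1, depth >= 1,
            prespacer_offset >= 1,
            prespacer_offset + 32 <= nchar(template_region))
  set.seed(seed)
  clone_variants <- sample(ALL_TRINUCS, n_clones, replace = TRUE)
  truth <- as.numeric(table(factor(clone_variants, levels = ALL_TRINUCS))) /
    n_clones
  names(truth) <- ALL_TRINUCS
  read_variants <- clone_variants[sample.int(n_clones, depth, replace = TRUE)]
  p0 <- prespacer_offset + randomized_window[1L] - 1L
  seqs <- template_region
  seqs <- vapply(read_variants, function(v) {
    s <- template_region
    substr(s, p0, p0 + 2L) <- v
    s
  }, character(1L), USE.NAMES = FALSE)
  seqs <- apply_substitutions(seqs, per_base_error)
  reads <- data.frame(id = sprintf("lib_%d", seq_len(depth)), seq = seqs,
                      qual = sample_quals(depth, nchar(template_region),
                                          qual_mean),
                      stringsAsFactors = FALSE)
  if (!is.null(out)) write_fastq(reads, out)
  list(reads = reads, truth = truth, path = out)
}

#' Simulate naive-adaptation spacer counts
#'
#' Naive adaptation has no strand bias and relaxed PAM specificity: reads are
#' split 50/50 between strands, a fraction `aag_pam_fraction` comes from
#' AAG-PAM prespacers within each strand, and per-prespacer rates are drawn
#' independently of internal AAG content.
#'
#' @param catalog full `prespacer_catalog` (both strands, all PAMs).
#' @param aag_pam_fraction fraction of reads from AAG-PAM prespacers
#'   (default 0.40).
#' @param n_reads reads per replicate.
#' @param seed RNG seed (also seeds the naive rate draw).
#' @param replicates number of replicates.
#' @param baseline_log_rate_sd sd of the lognormal naive rates.
#' @param consensus_pam PAM consensus (default `"AAG"`).
#' @return data.frame like [simulate_counts] output.
#' @export
simulate_naive_counts <- function(catalog, aag_pam_fraction = 0.40,
                                  n_reads, seed = 1L, replicates = 1L,
                                  baseline_log_rate_sd = 1.5,
                                  consensus_pam = "AAG") {
  stopifnot(n_reads > 0, aag_pam_fraction >= 0, aag_pam_fraction <= 1)
  is_aag <- catalog$pam == consensus_pam
  is_plus <- catalog$strand == "+"
  strata <- list(p_aag = which(is_plus & is_aag),
                 p_non = which(is_plus & !is_aag),
                 m_aag = which(!is_plus & is_aag),
                 m_non = which(!is_plus & !is_aag))
  if (aag_pam_fraction < 1 &&
      (length(strata$p_non) + length(strata$m_non)) == 0L)
    stop("catalog has no non-", consensus_pam,
         "-PAM prespacers (missing category: non-consensus PAM)")
  set.seed(seed)
  rate <- exp(rnorm(nrow(catalog), 0, baseline_log_rate_sd))
  counts <- matrix(0L, nrow(catalog), replicates,
                   dimnames = list(NULL, paste0("rep", seq_len(replicates))))
  for (r in seq_len(replicates)) {
    n_plus <- rbinom(1L, n_reads, 0.5)
    for (sd_name in c("p", "m")) {
      n_s <- if (sd_name == "p") n_plus else n_reads - n_plus
      n_aag <- rbinom(1L, n_s, aag_pam_fraction)
      i_aag <- strata[[paste0(sd_name, "_aag")]]
      i_non <- strata[[paste0(sd_name, "_non")]]
      counts[i_aag, r] <- counts[i_aag, r] + draw_stratum(n_aag, rate[i_aag])
      counts[i_non, r] <- counts[i_non, r] +
        draw_stratum(n_s - n_aag, rate[i_non])
    }
  }
  out <- as.data.frame(catalog)[, c("replicon", "start", "strand", "seq",
                                    "pam", "aag_r1", "aag_r2", "aag_r3")]
  ps <- attr(catalog, "priming_strand")
  out$nontarget <- if (is.null(ps)) NA else catalog$strand == ps
  out$naive_rate <- rate
  out <- cbind(out, as.data.frame(counts))
  rownames(out) <- NULL
  attr(out, "priming_strand") <- attr(catalog, "priming_strand")
  out
}
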