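# Generator: plasmids, prespacer catalogs, rates, counts, FASTQ output.

test_that("make_plasmid is deterministic, plants the protospacer, hits GC", {
  ps <- strrep("ACGTT", 7)
  ps <- substr(paste0(ps, ps), 1, 33)
  p1 <- make_plasmid(3000, 0.5, ps, priming_start = 40, seed = 1)
  p2 <- make_plasmid(3000, 0.5, ps, priming_start = 40, seed = 1)
  expect_identical(p1$sequence, p2$sequence)
  expect_identical(substr(p1$sequence, 41, 73), ps)

  # protospacer wrapping the origin is recoverable by circular reading
  pw <- make_plasmid(3000, 0.5, ps, priming_start = 2990, seed = 3)
  expect_identical(oracle_circ_window(pw$sequence, 2990, 33), ps)
  # and on the minus strand
  pm <- make_plasmid(3000, 0.5, ps, priming_start = 10,
                     priming_strand = "-", seed = 4)
  expect_identical(oracle_revcomp(oracle_circ_window(
    pm$sequence, (10 - 32) %% 3000, 33)), ps)

  # GC fraction within 3 points of the target (binomial bound at n = 3000)
  pg <- make_plasmid(3000, 0.7, ps, priming_start = 100, seed = 2)
  gc <- sum(strsplit(pg$sequence, "")[[1]] %in% c("G", "C")) / 3000
  expect_lt(abs(gc - 0.7), 0.03)

  expect_error(make_plasmid(150, 0.5, ps), "too small")
  expect_error(make_plasmid(3000, 0.5, substr(ps, 1, 30)), "33 ACGT")
})

test_that("catalog_prespacers matches a brute-force scan of all windows", {
  ps <- paste(rep("ACGTT", 7), collapse = "")
  ps <- substr(ps, 1, 33)
  for (seed in c(7, 8, 9)) {
    pl <- make_plasmid(500, 0.5, ps, priming_start = 50, seed = seed)
    cat_aag <- catalog_prespacers(pl, pam = "AAG")
    L <- pl$length
    # independent scan: every start on both strands, PAM from rotation/rc
    expected <- list()
    for (s0 in 0:(L - 1)) {
      wp <- oracle_circ_window(pl$sequence, s0, 33)
      pamp <- oracle_circ_window(pl$sequence, (s0 - 3) %% L, 3)
      if (pamp == "AAG")
        expected[[length(expected) + 1]] <- list(s0, "+", wp)
      wm <- oracle_revcomp(oracle_circ_window(pl$sequence, (s0 - 32) %% L, 33))
      pamm <- oracle_revcomp(oracle_circ_window(pl$sequence, (s0 + 1) %% L, 3))
      if (pamm == "AAG")
        expected[[length(expected) + 1]] <- list(s0, "-", wm)
    }
    exp_df <- do.call(rbind, lapply(expected, function(e)
      data.frame(start = e[[1]], strand = e[[2]], seq = e[[3]])))
    got <- cat_aag[, c("start", "strand", "seq")]
    rownames(got) <- rownames(exp_df) <- NULL
    o1 <- order(exp_df$start, exp_df$strand)
    o2 <- order(got$start, got$strand)
    expect_equal(got[o2, ], exp_df[o1, ], ignore_attr = TRUE)
  }
})

test_that("catalog handles planted and absent PAM cases", {
  fixed <- strrep("CA", 17)
  fixed <- substr(fixed, 1, 33)
  seqn <- paste0("AAG", fixed, strrep("CA", 100))
  pl <- plasmid_model("toy", seqn, priming_start = 3, priming_strand = "+",
                      priming_seq = fixed)
  cat_aag <- catalog_prespacers(pl, pam = "AAG")
  expect_true(any(cat_aag$seq == fixed & cat_aag$start == 3 &
                    cat_aag$strand == "+"))
  # alternating ACAC... has no AAG on either strand
  pl2 <- plasmid_model("empty", strrep("AC", 150), priming_start = 0,
                       priming_strand = "+",
                       priming_seq = substr(strrep("AC", 17), 1, 33))
  expect_identical(nrow(catalog_prespacers(pl2, pam = "AAG")), 0L)
})

test_that("catalog region counts sum to total internal AAG occurrences", {
  ps <- substr(strrep("ACGTT", 7), 1, 33)
  pl <- make_plasmid(600, 0.55, ps, priming_start = 50, seed = 11)
  cc <- catalog_prespacers(pl, pam = NULL)
  idx <- seq(1, nrow(cc), by = 37)
  for (i in idx) {
    tot <- oracle_count("AAG", cc$seq[i])
    expect_identical(cc$aag_r1[i] + cc$aag_r2[i] + cc$aag_r3[i], tot)
    # stored PAM equals the replicon-derived PAM (recompute independently)
    if (cc$strand[i] == "+") {
      expect_identical(cc$pam[i], oracle_circ_window(
        pl$sequence, (cc$start[i] - 3) %% 600, 3))
    } else {
      expect_identical(cc$pam[i], oracle_revcomp(oracle_circ_window(
        pl$sequence, (cc$start[i] + 1) %% 600, 3)))
    }
  }
})

test_that("assign_rates follows the log-linear penalty model", {
  ps <- substr(strrep("ACGTT", 7), 1, 33)
  pl <- make_plasmid(500, 0.5, ps, priming_start = 50, seed = 5)
  cc <- catalog_prespacers(pl, pam = NULL)
  # null model: no penalties, no baseline spread -> all rates equal
  m0 <- acquisition_model(baseline_log_rate_sd = 0, beta_region = c(0, 0, 0),
                          plasmid_fraction = 1, seed = 2)
  r0 <- assign_rates(cc, m0)
  expect_true(all(r0$rate == r0$rate[1]))

  # one region-1 AAG at penalty ln(10) lowers the rate 10-fold
  m1 <- acquisition_model(baseline_log_rate_sd = 0,
                          beta_region = c(log(10), 0, 0),
                          plasmid_fraction = 1, seed = 2)
  r1 <- assign_rates(cc, m1)
  one <- which(r1$aag_r1 == 1 & r1$aag_r2 == 0 & r1$aag_r3 == 0)[1]
  none <- which(r1$aag_r1 == 0 & r1$aag_r2 == 0 & r1$aag_r3 == 0)[1]
  expect_equal(r1$rate[one] / exp(r1$baseline[one]),
               0.1 * r1$rate[none] / exp(r1$baseline[none]))
  # determinism given the model seed
  expect_identical(assign_rates(cc, m1)$rate, r1$rate)
})

test_that("simulate_counts respects degenerate fractions and conserves reads", {
  st <- standard_sim(seed = 21, n_reads = 5000,
                     model = acquisition_model(strand_bias = 1,
                                               pam_fidelity = 1,
                                               plasmid_fraction = 1,
                                               seed = 31))
  sim <- st$sim
  on <- rowSums(sim[, c("rep1", "rep2")]) > 0
  expect_true(all(sim$nontarget[on]))
  expect_true(all(sim$pam[on] == "AAG"))
  expect_identical(unname(colSums(sim[, c("rep1", "rep2")])), c(5000, 5000))
})

test_that("simulate_counts errors name the missing category", {
  st <- standard_sim(seed = 22, n_reads = 100)
  expect_error(
    simulate_counts(st$rates, 100, acquisition_model(seed = 1), seed = 2),
    "missing category: host")
  aag_only <- st$rates[st$rates$pam == "AAG" &
                         st$rates$strand == st$plasmid$priming_strand, ]
  attr(aag_only, "priming_strand") <- st$plasmid$priming_strand
  expect_error(
    simulate_counts(aag_only, 100,
                    acquisition_model(plasmid_fraction = 1, seed = 1),
                    seed = 2),
    "missing category")
})

test_that("simulated strand bias is recovered at binomial precision", {
  st <- standard_sim(seed = 23, n_reads = 2e5, replicates = 1)
  sim <- st$sim
  nt <- sum(sim$rep1[sim$nontarget]) / sum(sim$rep1)
  se <- sqrt(0.8635 * (1 - 0.8635) / 2e5)
  expect_lt(abs(nt - 0.8635), 3 * se)
})

test_that("replicates without noise share expected proportions", {
  m <- acquisition_model(plasmid_fraction = 1, replicate_noise_sd = 0,
                         seed = 41)
  st <- standard_sim(seed = 24, n_reads = 2e5, replicates = 2, model = m)
  sim <- st$sim
  keep <- sim$nontarget & sim$pam == "AAG" & (sim$rep1 + sim$rep2) > 0
  r <- cor(log10(sim$rep1[keep] + 0.5), log10(sim$rep2[keep] + 0.5))
  expect_gt(r, 0.99)
})

test_that("array FASTQ output is deterministic and round-trips counts", {
  set.seed(60)
  tmpl <- array_template(random_dna(30), REPEAT_SEQ, random_dna(33),
                         random_dna(8), random_dna(8))
  counts <- c(150L, 60L, 25L)
  names(counts) <- vapply(1:3, function(i) random_dna(33), character(1))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_array_fastq(counts, tmpl, per_base_error = 0.001, qual_mean = 30,
                    out = f1, seed = 9)
  write_array_fastq(counts, tmpl, per_base_error = 0.001, qual_mean = 30,
                    out = f2, seed = 9)
  expect_identical(readLines(f1), readLines(f2))

  write_array_fastq(counts, tmpl, per_base_error = 0, qual_mean = 35,
                    out = f1, seed = 10)
  tab <- tally_spacers(extract_pool(read_fastq(f1),
                                    extraction_config(REPEAT_SEQ)))
  expect_identical(tab[sort(names(counts))], counts[sort(names(counts))])

  # low-quality reads are removed by the mean-Phred filter
  write_array_fastq(counts, tmpl, per_base_error = 0, qual_mean = 15,
                    out = f2, seed = 11)
  expect_identical(nrow(quality_filter(read_fastq(f2), 20)), 0L)
})

test_that("sequencing errors rarely break 2-mismatch repeat finding", {
  set.seed(61)
  tmpl <- array_template(random_dna(30), REPEAT_SEQ, random_dna(33),
                         random_dna(8), random_dna(8))
  counts <- structure(1000L, names = random_dna(33))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_array_fastq(counts, tmpl, per_base_error = 0.001, qual_mean = 35,
                    out = f, seed = 12)
  sp <- extract_pool(read_fastq(f), extraction_config(REPEAT_SEQ))
  # P(>=3 errors in one 29-bp repeat) ~ 3.6e-9; spacer errors dominate and
  # P(any error in the 33-mer) ~ 3.2%, so > 99% of reads yield a spacer and
  # > 95% the intended one
  expect_gt(length(sp) / 1000, 0.99)
  expect_gt(mean(sp == names(counts)), 0.95)
})

test_that("simulate_library truth sums to 1 and degenerate cases hold", {
  set.seed(62)
  region <- random_dna(120)
  lib1 <- simulate_library(region, prespacer_offset = 40,
                           randomized_window = 2:4, n_clones = 1,
                           depth = 50, seed = 3)
  expect_equal(sum(lib1$truth), 1)
  expect_identical(sum(lib1$truth > 0), 1L)
  expect_identical(length(unique(substr(lib1$reads$seq, 41, 43))), 1L)

  lib <- simulate_library(region, 40, 14:16, n_clones = 2000,
                          depth = 10000, seed = 4)
  expect_equal(sum(lib$truth), 1)
  obs <- table(factor(substr(lib$reads$seq, 53, 55),
                      levels = names(lib$truth))) / 10000
  # every variant within 4 binomial SDs of its truth fraction
  se <- sqrt(lib$truth * (1 - lib$truth) / 10000)
  expect_true(all(abs(as.numeric(obs) - lib$truth) <= 4 * se + 1e-12))

  expect_error(simulate_library(region, 40, 32:34, 10, 10, 1), "1..33")
  expect_error(simulate_library(region, 40, c(2, 4, 6), 10, 10, 1), "contiguous")
})

test_that("naive simulation has no strand bias and the stated PAM fraction", {
  ps <- substr(strrep("ACGTT", 7), 1, 33)
  pl <- make_plasmid(3000, 0.5, ps, priming_start = 100, seed = 71)
  cc <- catalog_prespacers(pl, pam = NULL)
  sim <- simulate_naive_counts(cc, aag_pam_fraction = 0.4, n_reads = 2e5,
                               seed = 72)
  tot <- sum(sim$rep1)
  expect_identical(tot, 2e5L)
  plus_frac <- sum(sim$rep1[sim$strand == "+"]) / tot
  expect_lt(abs(plus_frac - 0.5), 3 * sqrt(0.25 / 2e5))
  aag_frac <- sum(sim$rep1[sim$pam == "AAG"]) / tot
  expect_lt(abs(aag_frac - 0.4), 3 * sqrt(0.4 * 0.6 / 2e5))
})

test_that("naive and primed log frequencies are uncorrelated by design", {
  st <- standard_sim(seed = 25, n_reads = 5e4, replicates = 1)
  naive <- simulate_naive_counts(st$catalog, n_reads = 5e4, seed = 99)
  primed_tab <- sim_count_tables(st$sim)[[1]]
  naive_tab <- sim_count_tables(naive)[[1]]
  shared <- intersect(names(primed_tab), names(naive_tab))
  expect_gt(length(shared), 10)
  r <- cor(log10(as.numeric(primed_tab[shared])),
           log10(as.numeric(naive_tab[shared])))
  expect_lt(abs(r), 0.45)
})
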