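# spaceracq

Analysis of CRISPR spacer acquisition efficiency from amplicon sequencing,
for the *E. coli* type I-E system. The package takes FASTQ reads of expanded
CRISPR arrays, extracts newly acquired 33-nt spacers by repeat finding (≤2
mismatches), maps them exactly (0 mismatches) to circular replicons, keeps
uniquely mapped spacers, annotates PAM / strand class / 33-bp flanks, ranks
unique spacers into **hot** (top 25%) and **cold** (bottom 50%) categories,
and quantifies sequence determinants of acquisition — chiefly the avoidance
of internal AAG trinucleotides (the consensus PAM) in efficiently acquired
prespacers during primed adaptation.

For whom: experimentalists analysing primed/naive adaptation amplicon data,
and anyone needing a verifiable reference implementation of the statistics.

## The statistics at its core

For a k-mer *w*, pooled overlapping occurrence counts in hot vs cold
sequence sets form a 2×2 table (*w* vs all other windows) × (hot vs cold);
the package reports the two-sided Fisher exact p-value and the sample odds
ratio (Haldane +0.5 at zero cells). Positional structure is resolved two
ways:

- a 6-bp sliding window across prespacers and their 33-bp flanks, reporting
  ν<sub>h</sub> − ν<sub>c</sub> (mean AAG counts per window, hot minus cold)
  with Poisson SD √(ν<sub>h</sub>+ν<sub>c</sub>) and 95% bounds;
- Pearson correlations between AAG counts in three 11-bp prespacer regions
  and log<sub>10</sub> sampling frequency, with CIs and p-values via the
  Fisher z transformation, plus the whole-spacer R².

A seeded simulator (`make_plasmid`, `catalog_prespacers`, `assign_rates`,
`simulate_counts`, `write_array_fastq`, `simulate_library`,
`simulate_naive_counts`) generates the full experiment — log-linear
per-prespacer rates `log rate = N(0, σ) − Σ β_r · AAG_r`, 86.35% nontarget
strand bias, 98.4% AAG-PAM fidelity, 99.7% plasmid fraction — so every
stage is testable against ground truth.

## Worked example

```r
library(spaceracq)
set.seed(42)
priming <- random_dna(33)
plasmid <- make_plasmid(3000, gc = 0.5, priming_seq = priming,
                        priming_start = 100, priming_strand = "+", seed = 1)
catalog <- catalog_prespacers(plasmid, pam = NULL)   # all windows, both strands
model   <- acquisition_model(plasmid_fraction = 1, seed = 2)
rates   <- assign_rates(catalog, model)
sim     <- simulate_counts(rates, n_spacer_reads = 1e5, model,
                           replicates = 2, seed = 3)

summarize_simulated(sim)[1:3]
#> $plasmid_fraction [1] 1
#> $nontarget_fraction [1] 0.86491
#> $pam_fraction [1] 0.98383

ranked <- rank_simulated(sim)     # nontarget-strand AAG-PAM unique spacers
ranked
#> Ranked spacer table: 56 unique spacers (14 hot, 28 cold)

hot  <- ranked$seq[ranked$category == "hot"]
cold <- ranked$seq[ranked$category == "cold"]
subset(kmer_odds_ratios(hot, cold, k = 3), kmer %in% c("AAG", "CTT"))
#>  kmer count_hot other_hot count_cold other_cold odds_ratio      p_value
#>   AAG         1       433         27        841 0.07193568 0.0003247088
#>   CTT         8       426         15        853 1.06791862 1.0000000000

regional_correlations(ranked$seq, ranked$mean_log_freq)
#>      region          r      ci_lo       ci_hi     p_value  n
#>    upstream -0.4106919 -0.6079543 -0.16567517 0.001486254 56
#>      middle -0.1929336 -0.4338333  0.07371035 0.154908569 56
#>  downstream -0.3424065 -0.5553214 -0.08736609 0.009386125 56

variability_explained(ranked$seq, ranked$mean_log_freq)[c("r", "r_squared")]
#> r = -0.527, r^2 = 0.277
```

Reading the output: the simulated strand/PAM fractions are re-estimated
from the counts; AAG is strongly depleted in hot spacers (OR 0.07,
p = 3×10⁻⁴) while its complement CTT is not; the negative AAG–frequency
correlation is strongest in the PAM-proximal (upstream) 11 bp; and internal
AAG counts explain ~28% of the log-frequency variance in this run.

`extract_pool`/`tally_spacers` produce the same count tables from FASTQ
files written by `write_array_fastq`, and `pool_variant_freqs` /
`variant_odds_ratios` analyse randomized-trinucleotide library experiments.
See the vignette (`vignettes/primed-adaptation-pipeline.Rmd`) for the model,
parameter meanings, and design choices.

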