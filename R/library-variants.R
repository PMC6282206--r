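# Randomized-trinucleotide library analysis: variant frequencies in the
# plasmid pool (prespacer-region amplicons), variant frequencies among
# acquired spacers, per-variant odds ratios, and fold-change summaries for
# single-mutant constructs.

#' Library specification
#'
#' Describes one randomized-trinucleotide library: the reference 33-nt
#' prespacer, the randomized positions, and the flanking anchor sequences
#' used to locate the prespacer inside pool amplicon reads.
#'
#' @param reference_prespacer 33-nt ACGT string.
#' @param randomized_positions contiguous 1-based triple within 1..33.
#' @param flank_anchor_5p,flank_anchor_3p nonempty anchor sequences
#'   immediately flanking the prespacer in the amplicon.
#' @param max_anchor_mismatches Hamming budget for anchor location
#'   (default 2).
#' @return object of class `library_spec`.
#' @export
library_spec <- function(reference_prespacer, randomized_positions,
                         flank_anchor_5p, flank_anchor_3p,
                         max_anchor_mismatches = 2L) {
  randomized_positions <- as.integer(randomized_positions)
  if (!grepl("^[ACGT]{33}$", reference_prespacer))
    stop("reference_prespacer must be 33 ACGT bases")
  if (length(randomized_positions) != 3L ||
      any(diff(randomized_positions) != 1L) ||
      randomized_positions[1L] < 1L || randomized_positions[3L] > 33L)
    stop("randomized_positions must be a contiguous triple within 1..33")
  if (nchar(flank_anchor_5p) == 0L || nchar(flank_anchor_3p) == 0L)
    stop("anchors must be nonempty")
  structure(list(reference_prespacer = reference_prespacer,
                 randomized_positions = randomized_positions,
                 flank_anchor_5p = flank_anchor_5p,
                 flank_anchor_3p = flank_anchor_3p,
                 max_anchor_mismatches = as.integer(max_anchor_mismatches)),
            class = "library_spec")
}

#' Build a library_spec from a template region
#'
#' Convenience constructor taking the amplicon template and the prespacer's
#' 1-based offset in it; anchors are the flanking stretches of the template.
#'
#' @param template_region amplicon template containing the prespacer.
#' @param prespacer_offset 1-based start of the 33-nt prespacer.
#' @param randomized_positions contiguous 1-based triple within 1..33.
#' @param anchor_length anchor length on each side (default 20).
#' @param max_anchor_mismatches Hamming budget (default 2).
#' @return a [library_spec].
#' @export
library_spec_from_template <- function(template_region, prespacer_offset,
                                       randomized_positions,
                                       anchor_length = 20L,
                                       max_anchor_mismatches = 2L) {
  stopifnot(prespacer_offset - anchor_length >= 1,
            prespacer_offset + 32 + anchor_length <= nchar(template_region))
  library_spec(
    reference_prespacer = substr(template_region, prespacer_offset,
                                 prespacer_offset + 32L),
    randomized_positions = randomized_positions,
    flank_anchor_5p = substr(template_region,
                             prespacer_offset - anchor_length,
                             prespacer_offset - 1L),
    flank_anchor_3p = substr(template_region, prespacer_offset + 33L,
                             prespacer_offset + 32L + anchor_length),
    max_anchor_mismatches = max_anchor_mismatches)
}

# Locate the prespacer in one read via the 5' anchor (Hamming budget),
# confirming the 3' anchor right after the 33-mer. Returns the 33-mer or NA.
locate_prespacer <- function(seq, spec, rcseq = NULL) {
  a5 <- nchar(spec$flank_anchor_5p)
  a3 <- nchar(spec$flank_anchor_3p)
  if (is.null(rcseq)) rcseq <- revcomp(seq)
  try_hits <- function(s, hits5) {
    for (h in hits5) {
      ps <- h + a5           # prespacer start (1-based)
      pe <- ps + 32L
      if (pe + a3 > nchar(s)) next
      mm3 <- sum(utf8ToInt(substr(s, pe + 1L, pe + a3)) !=
                   utf8ToInt(spec$flank_anchor_3p))
      if (mm3 <= spec$max_anchor_mismatches)
        return(substr(s, ps, pe))
    }
    NA_character_
  }
  for (s in c(seq, rcseq)) {
    # exact-match fast path; the full Hamming scan only runs if it fails
    exact <- regexpr(spec$flank_anchor_5p, s, fixed = TRUE)
    if (exact > 0L) {
      r <- try_hits(s, exact)
      if (!is.na(r)) return(r)
    }
    full <- which(hamming_profile(s, spec$flank_anchor_5p) <=
                    spec$max_anchor_mismatches)
    r <- try_hits(s, full)
    if (!is.na(r)) return(r)
  }
  NA_character_
}

#' Variant frequencies in the plasmid pool
#'
#' Locates the prespacer in each pool amplicon read (either orientation,
#' anchors matched within the Hamming budget) and tabulates the bases at the
#' randomized positions over all 64 trinucleotide variants.
#'
#' @param reads data.frame `id`/`seq`/`qual` (e.g. from [read_fastq]) of
#'   prespacer-region amplicons.
#' @param spec a [library_spec].
#' @return list with `counts` (named integer over all 64 variants, zeros
#'   kept), `frequencies` (counts / located reads), `n_located`,
#'   `n_unlocated`.
#' @export
pool_variant_freqs <- function(reads, spec) {
  stopifnot(inherits(spec, "library_spec"))
  pos <- spec$randomized_positions
  rcs <- revcomp(reads$seq)
  found <- vapply(seq_along(reads$seq), function(i)
    locate_prespacer(reads$seq[i], spec, rcs[i]), character(1L))
  ok <- !is.na(found)
  if (!any(ok))
    stop("no read contained the anchored prespacer region")
  variants <- substr(found[ok], pos[1L], pos[3L])
  variants <- variants[variants %in% ALL_TRINUCS]
  counts <- table(factor(variants, levels = ALL_TRINUCS))
  counts <- structure(as.integer(counts), names = ALL_TRINUCS)
  list(counts = counts, frequencies = counts / sum(counts),
       n_located = sum(ok), n_unlocated = sum(!ok))
}

#' Variant frequencies among acquired spacers
#'
#' A spacer is counted as derived from the reference prespacer if it equals
#' it everywhere except (possibly) at the randomized triple; counts are
#' aggregated per trinucleotide variant.
#'
#' @param counts named integer vector of spacer read counts (names are
#'   33-nt spacer sequences), e.g. from [tally_spacers] or a ranked table.
#' @param spec a [library_spec].
#' @return list with `counts` (named integer over all 64 variants),
#'   `frequencies`, `n_matched` (reads), `n_other` (reads not derived from
#'   the reference prespacer).
#' @export
spacer_variant_freqs <- function(counts, spec) {
  stopifnot(inherits(spec, "library_spec"))
  pos <- spec$randomized_positions
  seqs <- names(counts)
  ref_masked <- spec$reference_prespacer
  substr(ref_masked, pos[1L], pos[3L]) <- "NNN"
  masked <- seqs
  is33 <- nchar(seqs) == 33L
  substr(masked[is33], pos[1L], pos[3L]) <- "NNN"
  match_ref <- is33 & masked == ref_masked
  variants <- substr(seqs[match_ref], pos[1L], pos[3L])
  v <- tapply(as.integer(counts[match_ref]),
              factor(variants, levels = ALL_TRINUCS), sum, default = 0L)
  v <- structure(as.integer(v), names = ALL_TRINUCS)
  tot <- sum(v)
  list(counts = v,
       frequencies = if (tot > 0) v / tot else v * NA_real_,
       n_matched = tot,
       n_other = sum(counts) - tot)
}

#' Per-variant odds ratios between acquired spacers and the plasmid pool
#'
#' For each of the 64 variants, a 2x2 table of (this variant vs all others)
#' x (acquired spacers vs pool) gives a two-sided Fisher exact p-value and
#' an odds ratio (Haldane +0.5 correction at zero cells). All 64 rows are
#' always present.
#'
#' @param pool_counts,spacer_counts named integer vectors over the same 64
#'   variants (e.g. `$counts` of [pool_variant_freqs] and
#'   [spacer_variant_freqs]).
#' @return data.frame (class `variant_table`) with columns `variant`,
#'   `pool_count`, `pool_freq`, `spacer_count`, `spacer_freq`,
#'   `odds_ratio`, `p_value`.
#' @export
variant_odds_ratios <- function(pool_counts, spacer_counts) {
  stopifnot(setequal(names(pool_counts), ALL_TRINUCS),
            setequal(names(spacer_counts), ALL_TRINUCS))
  pool <- as.integer(pool_counts[ALL_TRINUCS])
  spac <- as.integer(spacer_counts[ALL_TRINUCS])
  if (sum(pool) == 0L && sum(spac) == 0L)
    stop("both variant tables are all-zero")
  st <- mapply(function(a, c_) fisher_2x2(a, sum(spac) - a, c_,
                                          sum(pool) - c_),
               spac, pool, SIMPLIFY = FALSE)
  out <- data.frame(variant = ALL_TRINUCS,
                    pool_count = pool,
                    pool_freq = pool / sum(pool),
                    spacer_count = spac,
                    spacer_freq = spac / sum(spac),
                    odds_ratio = vapply(st, `[[`, numeric(1L), "odds_ratio"),
                    p_value = vapply(st, `[[`, numeric(1L), "p_value"))
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Aggregate variant odds ratios by AAG content
#'
#' One 2x2 table comparing variants that introduce an AAG at the randomized
#' window against all others (a coarser companion to the per-variant view).
#'
#' @param pool_counts,spacer_counts as in [variant_odds_ratios].
#' @param contains pattern whose presence in the variant defines the focal
#'   group (default `"AAG"`, i.e. the variant itself is AAG).
#' @return list with `odds_ratio`, `p_value`, and the four cell counts.
#' @export
variant_group_odds_ratio <- function(pool_counts, spacer_counts,
                                     contains = "AAG") {
  focal <- grepl(contains, ALL_TRINUCS, fixed = TRUE)
  a <- sum(spacer_counts[ALL_TRINUCS][focal])
  b <- sum(spacer_counts[ALL_TRINUCS][!focal])
  c_ <- sum(pool_counts[ALL_TRINUCS][focal])
  d <- sum(pool_counts[ALL_TRINUCS][!focal])
  c(fisher_2x2(a, b, c_, d),
    list(spacer_focal = a, spacer_other = b, pool_focal = c_,
         pool_other = d))
}

#' Fold-change summary for single-mutant constructs
#'
#' For each construct (wild type or an individual trinucleotide mutant),
#' the share of reference-prespacer-derived reads among all plasmid-derived
#' reads is computed per replicate; the mean, SD over replicates, and fold
#' change versus wild type are reported. A prespacer-derived read is one
#' whose spacer matches the construct's reference everywhere except the
#' mutated triple (see [spacer_variant_freqs]).
#'
#' @param constructs named list; each element is a list of replicate count
#'   vectors (named integer, names = spacer sequences) of plasmid-derived
#'   spacers for that construct. Must contain an element named `wt`.
#' @param spec a [library_spec] describing the reference prespacer and the
#'   mutated window.
#' @return data.frame with columns `construct`, `mean_share`, `sd_share`
#'   (`NA` with single replicates), `n_replicates`, `fold_vs_wt`.
#' @export
single_mutant_report <- function(constructs, spec) {
  stopifnot("wt" %in% names(constructs))
  share_of <- function(tab) {
    sv <- spacer_variant_freqs(tab, spec)
    (sv$n_matched) / sum(tab)
  }
  rows <- lapply(names(constructs), function(nm) {
    shares <- vapply(constructs[[nm]], share_of, numeric(1L))
    data.frame(construct = nm,
               mean_share = mean(shares),
               sd_share = if (length(shares) > 1L) stats::sd(shares)
                          else NA_real_,
               n_replicates = length(shares))
  })
  out <- do.call(rbind, rows)
  if (any(out$n_replicates < 2L))
    message("construct(s) with a single replicate: SD omitted")
  wt_share <- out$mean_share[out$construct == "wt"]
  out$fold_vs_wt <- out$mean_share / wt_share
  out
}
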