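# Glue between the simulator's count tables and the analysis surfaces, so
# the ranking and motif statistics can be driven either from extracted
# FASTQ reads or directly from simulated counts.

#' Per-replicate count vectors from a simulated count table
#'
#' @param sim output of [simulate_counts] or [simulate_naive_counts].
#' @param filter `"nontarget_AAG_only"` (the primed-adaptation analysis
#'   universe: nontarget-strand, consensus-PAM prespacers of the plasmid) or
#'   `"all"`.
#' @param consensus_pam PAM consensus (default `"AAG"`).
#' @param strand with `filter = "all"`, optionally restrict to one strand
#'   (`"+"`, `"-"`, or `NULL` for both).
#' @return list of named integer vectors (names are spacer sequences;
#'   rows sharing a sequence are aggregated), one per replicate.
#' @export
sim_count_tables <- function(sim, filter = c("nontarget_AAG_only", "all"),
                             consensus_pam = "AAG", strand = NULL) {
  filter <- match.arg(filter)
  keep <- rep(TRUE, nrow(sim))
  if (filter == "nontarget_AAG_only")
    keep <- sim$nontarget & sim$pam == consensus_pam
  if (!is.null(strand)) keep <- keep & sim$strand == strand
  rep_cols <- grep("^rep[0-9]+$", names(sim), value = TRUE)
  sub <- sim[keep, , drop = FALSE]
  lapply(rep_cols, function(cl) {
    v <- tapply(sub[[cl]], sub$seq, sum)
    v <- v[v > 0]
    structure(as.integer(v), names = names(v))
  })
}

#' Rank spacers from a simulated experiment
#'
#' Filters the simulated counts to the analysis universe, merges replicates
#' on the log scale, and ranks into hot/cold categories; prespacer
#' annotation columns are carried along for motif statistics.
#'
#' @param sim output of [simulate_counts].
#' @param cfg a [ranking_config].
#' @inheritParams sim_count_tables
#' @return a `ranked_spacer_table` with catalog annotation columns
#'   (`start`, `strand`, `pam`, AAG region counts) joined by sequence.
#' @export
rank_simulated <- function(sim, cfg = ranking_config(),
                           filter = c("nontarget_AAG_only", "all"),
                           consensus_pam = "AAG", strand = NULL) {
  tables <- sim_count_tables(sim, filter = filter,
                             consensus_pam = consensus_pam, strand = strand)
  merged <- merge_replicates(tables, pseudocount = cfg$pseudocount)
  ranked <- rank_and_categorize(merged, cfg)
  ann_cols <- c("seq", "replicon", "start", "strand", "pam",
                "aag_r1", "aag_r2", "aag_r3")
  ann <- as.data.frame(sim)[!duplicated(sim$seq), ann_cols, drop = FALSE]
  out <- merge(as.data.frame(ranked), ann, by = "seq", sort = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_spacer_table", "data.frame")
  out
}

#' Read-weighted mapping summary of a simulated count table
#'
#' Collapses a simulated count table into annotated hits and applies
#' [summarize_mapping], recovering the generator's plasmid, strand, and PAM
#' fractions.
#'
#' @param sim output of [simulate_counts].
#' @param consensus_pam PAM consensus (default `"AAG"`).
#' @return as [summarize_mapping].
#' @export
summarize_simulated <- function(sim, consensus_pam = "AAG") {
  rep_cols <- grep("^rep[0-9]+$", names(sim), value = TRUE)
  hits <- data.frame(seq = sim$seq, replicon = sim$replicon,
                     start = sim$start, strand = sim$strand,
                     count = as.integer(rowSums(sim[, rep_cols,
                                                    drop = FALSE])),
                     pam = sim$pam,
                     strand_class = ifelse(sim$nontarget, "nontarget",
                                           ifelse(sim$replicon ==
                                                    attr(sim, "replicon"),
                                                  "target",
                                                  "not_applicable")))
  summarize_mapping(hits, plasmid_name = attr(sim, "replicon"),
                    consensus_pam = consensus_pam)
}
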