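# Replicate merging on the log scale, cross-plasmid normalization to a
# common mean, and ranking of unique spacers into hot (top 25%) and cold
# (bottom 50%) categories.

#' Ranking configuration
#'
#' @param hot_frac top fraction labelled hot (default 0.25; size uses
#'   ceiling).
#' @param cold_frac bottom fraction labelled cold (default 0.50; size uses
#'   floor). `hot_frac + cold_frac` must not exceed 1.
#' @param pseudocount added to every count before log frequencies
#'   (default 0.5, Haldane-style, so unobserved replicate counts stay
#'   finite on the log scale).
#' @return object of class `ranking_config`.
#' @export
ranking_config <- function(hot_frac = 0.25, cold_frac = 0.50,
                           pseudocount = 0.5) {
  if (hot_frac <= 0 || cold_frac <= 0)
    stop("hot_frac and cold_frac must be positive")
  if (hot_frac + cold_frac > 1)
    stop("hot_frac + cold_frac must not exceed 1")
  structure(list(hot_frac = hot_frac, cold_frac = cold_frac,
                 pseudocount = pseudocount), class = "ranking_config")
}

#' Merge replicate count tables into mean log10 frequencies
#'
#' Per replicate, each spacer's sampling frequency is
#' (count + pseudocount) / (total + pseudocount * N) with N the number of
#' spacers in the union table; log10 frequencies are then averaged across
#' replicates (log-scale averaging). Spacers absent from every replicate
#' are excluded.
#'
#' @param tables list of named integer count vectors, one per replicate.
#' @param pseudocount see [ranking_config].
#' @return data.frame with columns `seq`, per-replicate counts
#'   `count_rep1..K`, per-replicate `logf_rep1..K`, and `mean_log_freq`.
#' @export
merge_replicates <- function(tables, pseudocount = 0.5) {
  stopifnot(length(tables) >= 1L)
  seqs <- sort(unique(unlist(lapply(tables, names))))
  if (length(seqs) == 0L)
    return(data.frame(seq = character(0), mean_log_freq = numeric(0)))
  counts <- vapply(tables, function(tab) {
    v <- tab[seqs]
    v[is.na(v)] <- 0L
    as.numeric(v)
  }, numeric(length(seqs)))
  counts <- matrix(counts, nrow = length(seqs))
  N <- length(seqs)
  logf <- vapply(seq_len(ncol(counts)), function(j) {
    log10((counts[, j] + pseudocount) /
            (sum(counts[, j]) + pseudocount * N))
  }, numeric(N))
  logf <- matrix(logf, nrow = N)
  out <- data.frame(seq = seqs)
  colnames(counts) <- paste0("count_rep", seq_len(ncol(counts)))
  colnames(logf) <- paste0("logf_rep", seq_len(ncol(logf)))
  out <- cbind(out, counts, logf)
  out$mean_log_freq <- rowMeans(logf)
  out
}

#' Normalize log-frequency tables from different plasmids to a common mean
#'
#' Each table's `mean_log_freq` column is shifted additively so every
#' table's mean equals the grand mean (mean of the per-table means);
#' within-table differences are unchanged. Empty tables are dropped with a
#' warning.
#'
#' @param tables list of data.frames with a `mean_log_freq` column.
#' @return the list with shifted `mean_log_freq` (original kept as
#'   `raw_log_freq`).
#' @export
normalize_sets <- function(tables) {
  nonempty <- vapply(tables, nrow, integer(1L)) > 0L
  if (any(!nonempty)) {
    warning(sum(!nonempty), " empty table(s) excluded from normalization")
    tables <- tables[nonempty]
  }
  if (length(tables) == 0L) return(tables)
  means <- vapply(tables, function(t) mean(t$mean_log_freq), numeric(1L))
  grand <- mean(means)
  for (i in seq_along(tables)) {
    tables[[i]]$raw_log_freq <- tables[[i]]$mean_log_freq
    tables[[i]]$mean_log_freq <- tables[[i]]$mean_log_freq +
      (grand - means[i])
  }
  tables
}

#' Rank spacers and assign hot/cold categories
#'
#' Spacers are sorted by descending `mean_log_freq`, ties broken by
#' lexicographic sequence order for determinism. The top
#' `ceiling(hot_frac * N)` are hot and the bottom `floor(cold_frac * N)`
#' cold; the remainder are mid.
#'
#' @param table data.frame with columns `seq` and `mean_log_freq` (e.g.
#'   from [merge_replicates]).
#' @param cfg a [ranking_config].
#' @return the table sorted by rank with added columns `rank` and
#'   `category` (class `ranked_spacer_table`).
#' @export
rank_and_categorize <- function(table, cfg = ranking_config()) {
  stopifnot(inherits(cfg, "ranking_config"), nrow(table) > 0)
  ord <- order(-table$mean_log_freq, table$seq)
  table <- table[ord, , drop = FALSE]
  N <- nrow(table)
  table$rank <- seq_len(N)
  n_hot <- ceiling(cfg$hot_frac * N)
  n_cold <- floor(cfg$cold_frac * N)
  category <- rep("mid", N)
  category[seq_len(n_hot)] <- "hot"
  if (n_cold > 0) category[(N - n_cold + 1L):N] <- "cold"
  table$category <- category
  rownames(table) <- NULL
  class(table) <- c("ranked_spacer_table", "data.frame")
  table
}

#' @export
print.ranked_spacer_table <- function(x, ...) {
  cat("Ranked spacer table: ", nrow(x), " unique spacers (",
      sum(x$category == "hot"), " hot, ",
      sum(x$category == "cold"), " cold)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Pearson correlation of log frequencies between two replicates
#'
#' Computed over the spacers shared by (observed in) both tables.
#'
#' @param table_a,table_b named count vectors, one per replicate.
#' @param pseudocount see [ranking_config].
#' @return list with `r`, `n_shared`; `r` is `NA` with a warning when fewer
#'   than 2 spacers are shared.
#' @export
replicate_correlation <- function(table_a, table_b, pseudocount = 0.5) {
  shared <- intersect(names(table_a), names(table_b))
  if (length(shared) < 2L) {
    warning("fewer than 2 shared spacers: correlation undefined")
    return(list(r = NA_real_, n_shared = length(shared)))
  }
  la <- log10((table_a[shared] + pseudocount) /
                (sum(table_a[shared]) + pseudocount * length(shared)))
  lb <- log10((table_b[shared] + pseudocount) /
                (sum(table_b[shared]) + pseudocount * length(shared)))
  list(r = as.numeric(stats::cor(la, lb)), n_shared = length(shared))
}
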