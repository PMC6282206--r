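# Exact mapping of 33-nt spacers to circular replicons (0 mismatches),
# uniqueness filtering, and annotation with PAM, 33-bp flanks, and strand
# class relative to the priming protospacer.

#' Exactly map a spacer to circular replicons
#'
#' Finds every exact occurrence on both strands of every replicon; matches
#' wrapping the origin are included (search over the doubled sequence).
#'
#' @param spacer spacer sequence.
#' @param replicons named character vector of circular replicon sequences.
#' @return data.frame with columns `replicon`, `start` (0-based position of
#'   spacer base 1 on its own strand), `strand`.
#' @export
map_exact <- function(spacer, replicons) {
  m <- nchar(spacer)
  rc <- revcomp(spacer)
  res <- list()
  for (nm in names(replicons)) {
    s <- replicons[[nm]]
    L <- nchar(s)
    if (m > L) next
    doubled <- paste0(s, substr(s, 1L, m - 1L))
    plus <- pattern_starts0(spacer, doubled)
    plus <- plus[plus < L]
    # rc(spacer) found at plus offset q means the spacer reads 5'->3' on the
    # minus strand with base 1 at plus coordinate (q + m - 1) mod L
    minus <- pattern_starts0(rc, doubled)
    minus <- (minus[minus < L] + m - 1L) %% L
    if (length(plus) || length(minus))
      res[[nm]] <- data.frame(
        replicon = nm,
        start = c(plus, minus),
        strand = rep(c("+", "-"), c(length(plus), length(minus))),
        stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(replicon = character(0), start = integer(0),
                      strand = character(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$replicon, out$start, match(out$strand, c("+", "-"))), ,
      drop = FALSE]
}

#' Keep uniquely mapped spacers
#'
#' A spacer is kept only if it has exactly one exact hit across all supplied
#' replicons jointly; 0 hits are rejected as unmapped and >= 2 as
#' multimappers, with the reason recorded.
#'
#' @param counts named integer vector (names = spacer sequences, values =
#'   read counts), e.g. from [tally_spacers].
#' @param replicons named character vector of circular replicon sequences.
#' @return list with `hits` (data.frame `seq`, `replicon`, `start`, `strand`,
#'   `count`) and `rejected` (data.frame `seq`, `count`, `reason`).
#' @export
keep_unique <- function(counts, replicons) {
  seqs <- names(counts)
  hit_rows <- vector("list", length(seqs))
  reason <- character(length(seqs))
  for (i in seq_along(seqs)) {
    h <- map_exact(seqs[i], replicons)
    if (nrow(h) == 1L) {
      h$seq <- seqs[i]
      h$count <- as.integer(counts[i])
      hit_rows[[i]] <- h
    } else {
      reason[i] <- if (nrow(h) == 0L) "unmapped" else "multimapper"
    }
  }
  kept <- hit_rows[!vapply(hit_rows, is.null, logical(1L))]
  hits <- if (length(kept)) do.call(rbind, kept) else
    data.frame(replicon = character(0), start = integer(0),
               strand = character(0), seq = character(0), count = integer(0))
  rownames(hits) <- NULL
  rej <- reason != ""
  list(hits = hits[, c("seq", "replicon", "start", "strand", "count"),
                   drop = FALSE],
       rejected = data.frame(seq = seqs[rej],
                             count = as.integer(counts[rej]),
                             reason = reason[rej]))
}

#' Annotate mapped spacers with PAM, flanks, and strand class
#'
#' The PAM is the 3 bases immediately 5' of the spacer on its own strand;
#' the upstream flank is the spacer-length window immediately beyond the
#' PAM and the downstream flank the window immediately 3' of the spacer,
#' both on the spacer's strand (circular). Hits on the replicon carrying the
#' priming protospacer are classed `nontarget` when they share the priming
#' protospacer's orientation (primed adaptation's dominant class), else
#' `target`; hits on other replicons are `not_applicable`.
#'
#' @param hits data.frame from [keep_unique] (`$hits`).
#' @param replicons named character vector of circular replicon sequences.
#' @param plasmid a [plasmid_model] defining the priming protospacer, or
#'   `NULL` for no strand classification.
#' @return `hits` with added columns `pam`, `strand_class`,
#'   `upstream_flank`, `downstream_flank`.
#' @export
annotate_hits <- function(hits, replicons, plasmid = NULL) {
  n <- nrow(hits)
  pam <- character(n)
  upf <- character(n)
  dnf <- character(n)
  cls <- rep("not_applicable", n)
  for (i in seq_len(n)) {
    s <- replicons[[hits$replicon[i]]]
    L <- nchar(s)
    m <- nchar(hits$seq[i])
    if (L < m + 3L + m)
      stop("replicon '", hits$replicon[i], "' too short (", L,
           " bp) to define PAM and ", m, "-bp flanks")
    st <- hits$start[i]
    if (hits$strand[i] == "+") {
      pam[i] <- circ_fetch(s, (st - 3L) %% L, 3L, "+")
      upf[i] <- circ_fetch(s, (st - 3L - m) %% L, m, "+")
      dnf[i] <- circ_fetch(s, (st + m) %% L, m, "+")
    } else {
      pam[i] <- circ_fetch(s, (st + 3L) %% L, 3L, "-")
      upf[i] <- circ_fetch(s, (st + 3L + m) %% L, m, "-")
      dnf[i] <- circ_fetch(s, (st - m) %% L, m, "-")
    }
    if (!is.null(plasmid) && hits$replicon[i] == plasmid$name)
      cls[i] <- if (hits$strand[i] == plasmid$priming_strand) "nontarget"
                else "target"
  }
  hits$pam <- pam
  hits$strand_class <- cls
  hits$upstream_flank <- upf
  hits$downstream_flank <- dnf
  hits
}

#' Summarize mapping fractions
#'
#' Read-weighted fractions over annotated hits: the fraction of reads mapping
#' to the priming plasmid, the nontarget-strand fraction among plasmid reads,
#' and the consensus-PAM fraction among plasmid reads.
#'
#' @param hits annotated hits (from [annotate_hits]) with `count`.
#' @param plasmid_name name of the priming plasmid replicon.
#' @param consensus_pam PAM consensus (default `"AAG"`).
#' @param weight `"reads"` (default) or `"spacers"` (each unique spacer
#'   counted once).
#' @return list with `plasmid_fraction`, `nontarget_fraction`,
#'   `pam_fraction`, `total_reads`, `plasmid_reads`; fractions are `NA` with
#'   a warning when their denominator is zero.
#' @export
summarize_mapping <- function(hits, plasmid_name, consensus_pam = "AAG",
                              weight = c("reads", "spacers")) {
  weight <- match.arg(weight)
  w <- if (weight == "reads") hits$count else rep(1L, nrow(hits))
  total <- sum(w)
  if (total == 0) {
    warning("zero mapped reads: fractions undefined")
    return(list(plasmid_fraction = NA_real_, nontarget_fraction = NA_real_,
                pam_fraction = NA_real_, total_reads = 0L,
                plasmid_reads = 0L))
  }
  on_pl <- hits$replicon == plasmid_name
  pl <- sum(w[on_pl])
  nt <- if (pl > 0) sum(w[on_pl & hits$strand_class == "nontarget"]) / pl
        else NA_real_
  pam <- if (pl > 0) sum(w[on_pl & hits$pam == consensus_pam]) / pl
         else NA_real_
  if (pl == 0) warning("zero plasmid reads: strand/PAM fractions undefined")
  list(plasmid_fraction = pl / total, nontarget_fraction = nt,
       pam_fraction = pam, total_reads = total, plasmid_reads = pl)
}
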