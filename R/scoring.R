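# Positional mismatch penalty score used to curate candidate target sites.
#
# Each duplex column is classified (Watson-Crick match, G:U wobble,
# mismatch, indel) and charged a penalty keyed to the miRNA position
# counted from the 5' end: wobble 0.5 anywhere, indel 2.0 anywhere,
# mismatch 1.5 inside the seed zone (positions 2-7), 1.0 elsewhere. The
# score of a site is the minimum penalty sum over every run of 20
# consecutive miRNA positions; sites scoring strictly below 3 are retained.

#' Scoring parameters for site curation
#'
#' Defaults are the published curation constants: G:U wobble 0.5 (not
#' counted as a mismatch), indel 2.0, mismatch 1.5 in the seed zone (miRNA
#' positions 2-7 from the 5' end) and 1.0 elsewhere; scores are computed
#' over every consecutive 20-nt window and the minimum kept; retention
#' requires score strictly below 3.
#'
#' @param wobble_penalty penalty for a G:U pair (any position).
#' @param indel_penalty penalty per gapped column (any position).
#' @param mismatch_seed_penalty mismatch penalty at positions
#'   `seed_range[1]`..`seed_range[2]`.
#' @param mismatch_other_penalty mismatch penalty elsewhere.
#' @param window_len window length in miRNA positions.
#' @param threshold strict upper bound for retention.
#' @param seed_range two integers, the seed zone (inclusive).
#' @param window_relative_seed if TRUE the seed zone is interpreted
#'   relative to each window's first position rather than the miRNA 5' end
#'   (sensitivity analysis only; default FALSE).
#' @return object of class `scoring_params`.
#' @export
scoring_params <- function(wobble_penalty = 0.5, indel_penalty = 2.0,
                           mismatch_seed_penalty = 1.5,
                           mismatch_other_penalty = 1.0,
                           window_len = 20L, threshold = 3.0,
                           seed_range = c(2L, 7L),
                           window_relative_seed = FALSE) {
  p <- list(wobble_penalty = wobble_penalty, indel_penalty = indel_penalty,
            mismatch_seed_penalty = mismatch_seed_penalty,
            mismatch_other_penalty = mismatch_other_penalty,
            window_len = as.integer(window_len), threshold = threshold,
            seed_range = as.integer(seed_range),
            window_relative_seed = isTRUE(window_relative_seed))
  stopifnot(p$wobble_penalty >= 0, p$indel_penalty >= 0,
            p$mismatch_seed_penalty >= 0, p$mismatch_other_penalty >= 0,
            p$window_len >= 1, p$threshold > 0,
            length(p$seed_range) == 2, p$seed_range[1] <= p$seed_range[2])
  class(p) <- "scoring_params"
  p
}

.score_eps <- 1e-9

#' Classify one duplex column
#'
#' Duplex orientation: the miRNA base is paired with the antisense target
#' base as presented in the alignment columns. T and U are equivalent.
#'
#' @param mirna_base miRNA base or "-" for a gap.
#' @param target_base target base or "-" for a gap.
#' @return one of "MATCH", "WOBBLE", "MISMATCH", "INDEL".
#' @export
classify_column <- function(mirna_base, target_base) {
  classify_columns(mirna_base, target_base)
}

#' Vectorized column classification
#' @param mirna_bases,target_bases parallel character vectors ("-" = gap).
#' @return character vector of pair classes.
#' @export
classify_columns <- function(mirna_bases, target_bases) {
  stopifnot(length(mirna_bases) == length(target_bases))
  if (any(mirna_bases == "-" & target_bases == "-")) {
    stop("column with gaps on both sides cannot be classified",
         call. = FALSE)
  }
  m <- chartr("T", "U", toupper(mirna_bases))
  t <- chartr("T", "U", toupper(target_bases))
  out <- rep("MISMATCH", length(m))
  out[m == "-" | t == "-"] <- "INDEL"
  wc <- (m == "A" & t == "U") | (m == "U" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G")
  out[wc] <- "MATCH"
  wob <- (m == "G" & t == "U") | (m == "U" & t == "G")
  out[wob] <- "WOBBLE"
  out
}

#' Penalty charged to one duplex column
#'
#' MATCH 0; WOBBLE `wobble_penalty` at any position; INDEL `indel_penalty`
#' at any position; MISMATCH `mismatch_seed_penalty` when the absolute
#' miRNA position falls in the seed zone, else `mismatch_other_penalty`.
#'
#' @param pair_class "MATCH", "WOBBLE", "MISMATCH" or "INDEL" (vectorized).
#' @param mirna_position 1-based position from the miRNA 5' end (ignored
#'   except for mismatches; may be NA for indel columns).
#' @param params a [scoring_params()] object.
#' @return numeric penalties.
#' @export
column_penalty <- function(pair_class, mirna_position,
                           params = scoring_params()) {
  pen <- numeric(length(pair_class))
  pen[pair_class == "WOBBLE"] <- params$wobble_penalty
  pen[pair_class == "INDEL"] <- params$indel_penalty
  mm <- pair_class == "MISMATCH"
  in_seed <- !is.na(mirna_position) &
    mirna_position >= params$seed_range[1] &
    mirna_position <= params$seed_range[2]
  pen[mm & in_seed] <- params$mismatch_seed_penalty
  pen[mm & !in_seed] <- params$mismatch_other_penalty
  pen
}

#' Windowed penalty score of a duplex alignment
#'
#' For every run of `window_len` consecutive miRNA positions (an L-nt miRNA
#' has L - window_len + 1 windows), the penalties of all columns consuming
#' those positions are summed, plus any insertion columns (miRNA-gap) lying
#' strictly between the window's first and last consumed positions. The
#' site score is the minimum over windows. Seed-zone mismatch penalties are
#' keyed to the absolute miRNA position, not the window-relative one.
#'
#' @param aln a [duplex_alignment()].
#' @param params a [scoring_params()] object.
#' @return list of class `site_score` with elements `score`,
#'   `best_window_start` (1-based miRNA position opening the minimizing
#'   window) and `per_window_scores`.
#' @export
score_duplex <- function(aln, params = scoring_params()) {
  cols <- aln$columns
  L <- aln$mirna_length
  covered <- sum(!is.na(cols$mirna_pos))
  if (covered < params$window_len) {
    stop(sprintf("alignment covers %d miRNA positions; %d needed to score",
                 covered, params$window_len), call. = FALSE)
  }
  cls <- classify_columns(cols$mirna, cols$target)
  # anchor each insertion column between its flanking miRNA positions
  pos <- cols$mirna_pos
  prev_pos <- cummax(ifelse(is.na(pos), 0L, pos))          # last consumed
  next_pos <- rev(cummin(rev(ifelse(is.na(pos), L + 1L, pos))))  # next
  maxpos <- max(pos, na.rm = TRUE)
  n_win <- maxpos - params$window_len + 1L
  if (n_win < 1L) {
    stop("fewer miRNA positions covered than one scoring window",
         call. = FALSE)
  }
  per_window <- vapply(seq_len(n_win), function(w) {
    lo <- w
    hi <- w + params$window_len - 1L
    eff_pos <- if (params$window_relative_seed) pos - lo + 1L else pos
    pen <- column_penalty(cls, eff_pos, params)
    in_win <- !is.na(pos) & pos >= lo & pos <= hi
    ins_in <- is.na(pos) & prev_pos >= lo & next_pos <= hi
    sum(pen[in_win | ins_in])
  }, numeric(1))
  best <- which.min(per_window)
  out <- list(score = per_window[best], best_window_start = best,
              per_window_scores = per_window)
  class(out) <- "site_score"
  out
}

#' Curate scored sites at the strict retention threshold
#'
#' Retains exactly the sites whose score is strictly below the threshold
#' (score 3.0 is rejected at the default threshold of 3). Input order is
#' preserved; the operation is idempotent.
#'
#' @param sites either a data.frame with a `score` column, or a list whose
#'   elements carry `$score` (e.g. pairs of alignment and `site_score`).
#' @param params a [scoring_params()] object.
#' @return the retained subset, same shape as the input.
#' @export
curate <- function(sites, params = scoring_params()) {
  scores <- if (is.data.frame(sites)) {
    sites$score
  } else {
    vapply(sites, function(s) {
      if (is.numeric(s$score)) s$score else s$score$score
    }, numeric(1))
  }
  keep <- scores < params$threshold - .score_eps
  if (is.data.frame(sites)) sites[keep, , drop = FALSE] else sites[keep]
}
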