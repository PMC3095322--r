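# Antisense duplex scanner.
#
# Candidate duplexes are found by a banded local DP over each target strand
# (miRNA-global, target-local), with rewards on a miRanda-like scale. The
# scanner only proposes candidate sites; curation is entirely delegated to
# the downstream positional penalty score, so the published curation rules
# apply regardless of how candidates were found.

#' Scanner parameters
#'
#' Dynamic-programming rewards/penalties (integer scale, internal to the
#' scanner) and candidate-site policy. Defaults: Watson-Crick pair +5, G:U
#' wobble +2, mismatch -3, gap open -8, gap extend -2; at least 90% of
#' miRNA positions must be paired; at most 3 indel columns per duplex; at
#' most 20 sites kept per miRNA x target pair after merging.
#'
#' @param pair_reward,wobble_reward,mismatch_penalty,gap_open,gap_extend
#'   integer DP scores; rewards positive, penalties negative.
#' @param min_mirna_coverage minimum fraction of miRNA positions paired
#'   (Watson-Crick or wobble) for a candidate to be reported.
#' @param max_sites_per_pair cap on merged sites per miRNA x target pair.
#' @param band_width maximum number of indel columns in one duplex.
#' @return object of class `scan_params`.
#' @export
scan_params <- function(pair_reward = 5L, wobble_reward = 2L,
                        mismatch_penalty = -3L, gap_open = -8L,
                        gap_extend = -2L, min_mirna_coverage = 0.9,
                        max_sites_per_pair = 20L, band_width = 3L) {
  p <- list(pair_reward = as.integer(pair_reward),
            wobble_reward = as.integer(wobble_reward),
            mismatch_penalty = as.integer(mismatch_penalty),
            gap_open = as.integer(gap_open),
            gap_extend = as.integer(gap_extend),
            min_mirna_coverage = as.numeric(min_mirna_coverage),
            max_sites_per_pair = as.integer(max_sites_per_pair),
            band_width = as.integer(band_width))
  stopifnot(p$pair_reward > 0, p$wobble_reward > 0,
            p$mismatch_penalty < 0, p$gap_open < 0, p$gap_extend < 0,
            p$min_mirna_coverage > 0, p$min_mirna_coverage <= 1,
            p$band_width >= 0, p$max_sites_per_pair >= 1)
  class(p) <- "scan_params"
  p
}

#' Construct a duplex alignment object
#'
#' Columns are ordered 5'->3' along the miRNA, so the paired target bases
#' run 3'->5' on the pairing strand. `target_start`/`target_end` are always
#' 1-based inclusive in the plus-strand frame of the target sequence;
#' `strand` says which strand carries the site.
#'
#' @param mirna_id,target_id identifiers.
#' @param target_start,target_end site coordinates (plus-strand frame).
#' @param strand "+" or "-".
#' @param mirna_bases,target_bases parallel character vectors, one entry
#'   per column, "-" for a gap.
#' @param mirna_positions 1-based miRNA position consumed by each column
#'   (NA for columns where the miRNA has a gap).
#' @param mirna_length length of the mature miRNA.
#' @return object of class `duplex_alignment`.
#' @export
duplex_alignment <- function(mirna_id, target_id, target_start, target_end,
                             strand, mirna_bases, target_bases,
                             mirna_positions, mirna_length) {
  stopifnot(length(mirna_bases) == length(target_bases),
            length(mirna_positions) == length(mirna_bases),
            strand %in% c("+", "-"), target_end >= target_start)
  if (any(mirna_bases == "-" & target_bases == "-")) {
    stop("alignment column with gaps on both sides", call. = FALSE)
  }
  covered <- sum(mirna_bases != "-")
  if (covered != sum(!is.na(mirna_positions))) {
    stop("mirna_positions inconsistent with gap columns", call. = FALSE)
  }
  aln <- list(mirna_id = mirna_id, target_id = target_id,
              target_start = as.integer(target_start),
              target_end = as.integer(target_end), strand = strand,
              columns = data.frame(mirna = mirna_bases,
                                   target = target_bases,
                                   mirna_pos = as.integer(mirna_positions),
                                   stringsAsFactors = FALSE),
              mirna_length = as.integer(mirna_length))
  class(aln) <- "duplex_alignment"
  aln
}

#' Render a duplex alignment as three text lines
#'
#' miRNA on top 5'->3', target below 3'->5'; '|' marks Watson-Crick pairs,
#' ':' marks G:U wobbles, ' ' anything else.
#'
#' @param aln a `duplex_alignment`.
#' @return single string with three newline-separated lines.
#' @export
render_alignment <- function(aln) {
  cls <- classify_columns(aln$columns$mirna, aln$columns$target)
  bars <- ifelse(cls == "MATCH", "|", ifelse(cls == "WOBBLE", ":", " "))
  paste(
    paste0("miR 5' ", paste(aln$columns$mirna, collapse = ""), " 3'"),
    paste0("       ", paste(bars, collapse = "")),
    paste0("tgt 3' ", paste(aln$columns$target, collapse = ""), " 5'"),
    sep = "\n")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("<duplex> %s x %s [%d-%d] (%s)\n", x$mirna_id, x$target_id,
              x$target_start, x$target_end, x$strand))
  cat(render_alignment(x), "\n")
  invisible(x)
}

# scan-space preparation: a string walked left-to-right visits the target
# bases pairing miRNA positions 1..L in order.
#   plus strand:  S = reverse(T);    S span [a,b] <-> plus span [n-b+1, n-a+1]
#   minus strand: S = complement(T); S span [a,b] <-> plus span [a, b]
.scan_space <- function(target_seq, strand) {
  if (strand == "+") .reverse_chars(target_seq) else
    complement_dna(target_seq)
}

.mirna_arg <- function(mirna) {
  if (is.data.frame(mirna)) mirna <- as.list(mirna[1, ])
  stopifnot(!is.null(mirna$id), !is.null(mirna$sequence))
  mirna$sequence <- normalize_rna(mirna$sequence)
  mirna
}

.target_arg <- function(target) {
  if (is.data.frame(target)) target <- as.list(target[1, ])
  stopifnot(!is.null(target$id), !is.null(target$sequence))
  if (is.null(target$kind)) target$kind <- "UNIGENE"
  target$sequence <- normalize_dna(target$sequence)
  target
}

# turn one kernel row into a duplex_alignment (coordinates mapped back to
# the plus-strand frame)
.candidate_to_alignment <- function(mseq, S, n, strand, mirna_id, target_id,
                                    anchor, tend, ops, dp_score = NA_integer_) {
  op <- strsplit(ops, "", fixed = TRUE)[[1]]
  mir_pos <- ifelse(op == "I", NA_integer_, cumsum(op != "I"))
  t_off <- cumsum(op != "D")                 # target consumption count
  t_pos <- ifelse(op == "D", NA_integer_, anchor + t_off - 1L)
  m_chars <- strsplit(mseq, "", fixed = TRUE)[[1]]
  s_chars <- strsplit(S, "", fixed = TRUE)[[1]]
  mirna_bases <- ifelse(is.na(mir_pos), "-", m_chars[ifelse(is.na(mir_pos), 1L, mir_pos)])
  target_bases <- ifelse(is.na(t_pos), "-", s_chars[ifelse(is.na(t_pos), 1L, t_pos)])
  if (strand == "+") {
    ts <- n - tend + 1L
    te <- n - anchor + 1L
  } else {
    ts <- anchor
    te <- tend
  }
  aln <- duplex_alignment(mirna_id, target_id, ts, te, strand,
                          mirna_bases, target_bases, mir_pos, nchar(mseq))
  aln$dp_score <- as.integer(dp_score)
  aln
}

.scan_one_strand <- function(mseq, target_seq, strand, mirna_id, target_id,
                             params, kernel) {
  S <- .scan_space(target_seq, strand)
  n <- nchar(S)
  res <- kernel(mseq, S, unclass(params))
  k <- length(res$anchor)
  if (k == 0) return(list())
  lapply(seq_len(k), function(i) {
    .candidate_to_alignment(mseq, S, n, strand, mirna_id, target_id,
                            res$anchor[i], res$tend[i], res$ops[i],
                            res$score[i])
  })
}

# merge candidates of one miRNA x target x strand whose plus-frame starts
# chain within `window` nt: keep the lowest penalty score; ties go to the
# highest scanner alignment score (so a perfect duplex beats a variant of
# the same locus padded with window-excluded terminal defects), then to
# the leftmost start, then the shortest span (fully deterministic).
.merge_candidates <- function(alns, scores, window = 3L) {
  if (length(alns) == 0) return(integer(0))
  ord <- order(vapply(alns, `[[`, 1L, "target_start"))
  starts <- vapply(alns, `[[`, 1L, "target_start")[ord]
  cluster <- cumsum(c(1L, as.integer(diff(starts) > window)))
  keep <- integer(0)
  for (cl in unique(cluster)) {
    idx <- ord[cluster == cl]
    dp <- vapply(alns[idx], function(a) a$dp_score %||% NA_integer_,
                 integer(1))
    st <- vapply(alns[idx], `[[`, 1L, "target_start")
    en <- vapply(alns[idx], `[[`, 1L, "target_end")
    best <- idx[order(scores[idx], -dp, st, en - st)][1]
    keep <- c(keep, best)
  }
  sort(keep)
}

.scan_engine <- function(mirna, target, params, kernel) {
  mirna <- .mirna_arg(mirna)
  target <- .target_arg(target)
  if (nchar(target$sequence) < 20L) {
    warning(sprintf("target %s shorter than 20 nt: no scan performed",
                    target$id), call. = FALSE)
    return(list())
  }
  if (nchar(mirna$sequence) < 20L) {
    warning(sprintf("miRNA %s shorter than the 20-nt scoring window: skipped",
                    mirna$id), call. = FALSE)
    return(list())
  }
  strands <- if (identical(target$kind, "BAC")) c("+", "-") else "+"
  out <- list()
  for (strand in strands) {
    cands <- .scan_one_strand(mirna$sequence, target$sequence, strand,
                              mirna$id, target$id, params, kernel)
    if (length(cands) == 0) next
    scores <- vapply(cands, function(a) score_duplex(a)$score, numeric(1))
    keep <- .merge_candidates(cands, scores)
    out <- c(out, cands[keep])
  }
  if (length(out) > 0) {
    scores <- vapply(out, function(a) score_duplex(a)$score, numeric(1))
    ord <- order(scores, vapply(out, `[[`, 1L, "target_start"))
    out <- out[ord[seq_len(min(length(out), params$max_sites_per_pair))]]
    # stable reporting order: by coordinate
    out <- out[order(vapply(out, `[[`, 1L, "target_start"),
                     vapply(out, `[[`, "", "strand"))]
  }
  out
}

#' Scan one target sequence for antisense duplexes of one miRNA
#'
#' Banded dynamic-programming search for candidate miRNA:target duplexes.
#' BAC targets are scanned on both strands, unigenes on the sense strand
#' only. Overlapping candidates of the same miRNA within 3 nt are merged,
#' keeping the one with the lowest downstream penalty score (ties to the
#' leftmost start). Candidates are reported regardless of the curation
#' threshold; apply [curate()] after [score_duplex()].
#'
#' @param mirna one-row data.frame or list with `id` and `sequence`.
#' @param target one-row data.frame or list with `id`, `kind`, `sequence`.
#' @param params a [scan_params()] object.
#' @return list of [duplex_alignment()] objects (possibly empty).
#' @export
scan <- function(mirna, target, params = scan_params()) {
  .scan_engine(mirna, target, params, .scan_kernel_dp)
}

#' Exhaustive reference scan (test oracle)
#'
#' Enumerates, per anchor, every gap placement within the indel band and
#' returns the same merged candidate set as [scan()]. Quadratic blow-up is
#' guarded: targets longer than `guard` nt are refused.
#'
#' @inheritParams scan
#' @param guard maximum target length accepted (default 10000 nt).
#' @return list of [duplex_alignment()] objects.
#' @export
scan_exhaustive <- function(mirna, target, params = scan_params(),
                            guard = 10000L) {
  target <- .target_arg(target)
  if (nchar(target$sequence) > guard) {
    stop(sprintf("scan_exhaustive refused: target %s is %d nt (> %d nt guard)",
                 target$id, nchar(target$sequence), guard), call. = FALSE)
  }
  .scan_engine(mirna, target, params, .scan_kernel_exhaustive)
}

#' Scan all miRNAs against all targets
#'
#' @param mirnas data.frame from [read_mirna_fasta()].
#' @param targets data.frame from [read_target_fasta()] (may mix kinds if a
#'   `kind` column is present).
#' @param params a [scan_params()] object.
#' @return list with `sites` (data.frame: site_id, mirna_id, target_id,
#'   target_kind, strand, start, end, score) and `alignments` (named list
#'   of `duplex_alignment`, keyed by site_id). Scores are the windowed
#'   penalty scores; no curation threshold is applied here.
#' @export
scan_all <- function(mirnas, targets, params = scan_params()) {
  alns <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(targets))) {
      hits <- scan(mirnas[i, ], targets[j, ], params)
      alns <- c(alns, hits)
    }
  }
  if (length(alns) == 0) {
    return(list(sites = data.frame(site_id = character(),
                                   mirna_id = character(),
                                   target_id = character(),
                                   target_kind = character(),
                                   strand = character(), start = integer(),
                                   end = integer(), score = numeric(),
                                   stringsAsFactors = FALSE),
                alignments = list()))
  }
  kind_of <- stats::setNames(as.character(targets$kind), targets$id)
  sites <- data.frame(
    mirna_id = vapply(alns, `[[`, "", "mirna_id"),
    target_id = vapply(alns, `[[`, "", "target_id"),
    strand = vapply(alns, `[[`, "", "strand"),
    start = vapply(alns, `[[`, 1L, "target_start"),
    end = vapply(alns, `[[`, 1L, "target_end"),
    stringsAsFactors = FALSE)
  sites$target_kind <- unname(kind_of[sites$target_id])
  sites$score <- vapply(alns, function(a) score_duplex(a)$score, numeric(1))
  ord <- order(sites$mirna_id, sites$target_id, sites$start, sites$strand)
  sites <- sites[ord, ]
  alns <- alns[ord]
  sites$site_id <- sprintf("site%04d", seq_len(nrow(sites)))
  rownames(sites) <- NULL
  names(alns) <- sites$site_id
  list(sites = sites[, c("site_id", "mirna_id", "target_id", "target_kind",
                         "strand", "start", "end", "score")],
       alignments = alns)
}
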