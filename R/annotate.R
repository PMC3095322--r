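# Gene-model annotation of curated target sites.
#
# A site is called "yes" when its interval shares at least one base with a
# predicted gene, strand-agnostic. Six prediction channels are tracked
# separately (four Augustus runs, GenomeThreader, BLASTX vs Arabidopsis
# peptides); the aggregate flag is the OR over a configurable channel set
# defaulting to all six.

#' Annotate curated sites against predicted gene features
#'
#' Per-channel flags are TRUE iff the site interval (1-based inclusive)
#' overlaps >= 1 nt of a feature from that channel on the same sequence,
#' regardless of strand. The hit definition concatenates the definitions of
#' all overlapping features, deduplicated, ordered by feature start then
#' source (diff-stable exports).
#'
#' @param sites data.frame with columns site_id, target_id, start, end
#'   (e.g. `scan_all()$sites`).
#' @param features data.frame of gene features (seq_id, source, start, end,
#'   strand, hit_definition), e.g. `read_gff3_features()$genes`.
#' @param aggregate_channels channels contributing to the aggregate
#'   `gene_hit` flag (default: all six).
#' @return data.frame with site_id, one logical column `hit_<channel>` per
#'   channel, `gene_hit` (aggregate), and `hit_definition`.
#' @export
annotate_sites <- function(sites, features,
                           aggregate_channels = annotation_channels()) {
  channels <- annotation_channels()
  stopifnot(all(aggregate_channels %in% channels))
  if (nrow(features) > 0 && !all(features$source %in% channels)) {
    stop(sprintf("unknown annotation channel(s): %s",
                 paste(setdiff(unique(features$source), channels),
                       collapse = ", ")), call. = FALSE)
  }
  flag_cols <- paste0("hit_", tolower(channels))
  out <- data.frame(site_id = sites$site_id, stringsAsFactors = FALSE)
  for (fc in flag_cols) out[[fc]] <- logical(nrow(sites))
  out$gene_hit <- logical(nrow(sites))
  out$hit_definition <- character(nrow(sites))
  if (nrow(sites) == 0) return(out)
  site_ir <- IRanges::IRanges(start = sites$start, end = sites$end)
  feat_ir <- if (nrow(features) > 0) {
    IRanges::IRanges(start = features$start, end = features$end)
  } else {
    IRanges::IRanges()
  }
  ov <- IRanges::findOverlaps(site_ir, feat_ir, minoverlap = 1L)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  same_seq <- sites$target_id[qh] == features$seq_id[sh]
  qh <- qh[same_seq]
  sh <- sh[same_seq]
  for (i in seq_len(nrow(sites))) {
    fidx <- sh[qh == i]
    if (length(fidx) == 0) next
    hit_src <- features$source[fidx]
    for (ch in unique(hit_src)) {
      out[[paste0("hit_", tolower(ch))]][i] <- TRUE
    }
    ord <- order(features$start[fidx], features$source[fidx])
    defs <- features$hit_definition[fidx][ord]
    defs <- defs[nzchar(defs)]
    out$hit_definition[i] <- paste(unique(defs), collapse = "; ")
  }
  agg <- paste0("hit_", tolower(aggregate_channels))
  out$gene_hit <- Reduce(`|`, out[agg])
  out
}

#' Annotate a single site
#'
#' Convenience wrapper around [annotate_sites()] for one site; errors if
#' the features are not on the site's sequence coordinate frame.
#'
#' @param site list or one-row data.frame with site_id, target_id, start,
#'   end.
#' @param features gene feature data.frame (must be on `site$target_id`).
#' @param ... passed to [annotate_sites()].
#' @return one-row annotation data.frame.
#' @export
annotate_site <- function(site, features, ...) {
  if (is.data.frame(site)) site <- as.list(site[1, ])
  if (nrow(features) > 0 && !all(features$seq_id == site$target_id)) {
    stop(sprintf("features are not on sequence %s", site$target_id),
         call. = FALSE)
  }
  sites <- data.frame(site_id = site$site_id %||% "site",
                      target_id = site$target_id,
                      start = site$start, end = site$end,
                      stringsAsFactors = FALSE)
  annotate_sites(sites, features, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
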