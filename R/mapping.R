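# Genetic-map placement: BACs onto BINs via anchored markers, unigenes via
# identity/coverage-filtered alignments to anchored BACs, and curation of
# putative precursor hits by e-value.

#' Mapping and precursor-curation thresholds
#'
#' Published values: unigene placement requires >= 90% identity and >= 95%
#' query coverage (inclusive); precursor hits are kept at expect value
#' <= 1e-50.
#'
#' @param min_identity percent identity threshold (inclusive).
#' @param min_coverage percent query-coverage threshold (inclusive).
#' @param precursor_evalue_cutoff inclusive e-value ceiling.
#' @return object of class `mapping_params`.
#' @export
mapping_params <- function(min_identity = 90.0, min_coverage = 95.0,
                           precursor_evalue_cutoff = 1e-50) {
  p <- list(min_identity = min_identity, min_coverage = min_coverage,
            precursor_evalue_cutoff = precursor_evalue_cutoff)
  stopifnot(p$min_identity > 0, p$min_identity <= 100,
            p$min_coverage > 0, p$min_coverage <= 100,
            p$precursor_evalue_cutoff > 0)
  class(p) <- "mapping_params"
  p
}

.bin_assignment <- function(seq_id, bin_ids, evidence) {
  out <- list(seq_id = seq_id, bin_ids = sort(unique(bin_ids)),
              evidence = evidence)
  class(out) <- "bin_assignment"
  out
}

#' Place a BAC on genetic BINs via its anchored markers
#'
#' BINs are the union over markers of both genetic maps (EXPEN1992 and
#' EXPEN2000); a BAC carrying markers from several BINs keeps them all. A
#' BAC with no markers is returned unassigned (empty BIN set).
#'
#' @param bac_id BAC identifier.
#' @param markers marker data.frame (name, map_name, seq_id, position,
#'   bin_id), e.g. from [read_marker_map()]; rows for other BACs are
#'   ignored.
#' @return object of class `bin_assignment` with `seq_id`, `bin_ids`
#'   (character, possibly empty) and `evidence` (the marker rows used).
#' @export
assign_bac_bins <- function(bac_id, markers) {
  mk <- markers[markers$seq_id == bac_id & !is.na(markers$bin_id) &
                  nzchar(markers$bin_id), , drop = FALSE]
  if (nrow(mk) == 0) {
    message(sprintf("BAC %s has no anchored markers: unassigned", bac_id))
    return(.bin_assignment(bac_id, character(0),
                           mk[, c("name", "map_name", "bin_id"),
                              drop = FALSE]))
  }
  mk <- mk[order(mk$name, mk$map_name), , drop = FALSE]
  .bin_assignment(bac_id, mk$bin_id,
                  mk[, c("name", "map_name", "bin_id"), drop = FALSE])
}

#' Place a unigene on BINs via filtered alignments to anchored BACs
#'
#' Hits passing both thresholds (identity >= `min_identity` AND coverage >=
#' `min_coverage`, boundaries inclusive) let the unigene inherit every BIN
#' of the matched BAC.
#'
#' @param unigene_id unigene identifier.
#' @param hits placement hits for this unigene, as from [read_blast_tab()]
#'   (needs columns sseqid, pident, coverage).
#' @param bac_assignments named list of `bin_assignment` objects (or a
#'   data.frame with seq_id, bin_id columns) giving each BAC's BINs.
#' @param params a [mapping_params()] object.
#' @return object of class `bin_assignment`; `evidence` is a data.frame of
#'   passing placements (bac_id, identity, coverage).
#' @export
place_unigene <- function(unigene_id, hits, bac_assignments,
                          params = mapping_params()) {
  eps <- 1e-9
  if (nrow(hits) > 0) {
    hits <- hits[hits$qseqid == unigene_id, , drop = FALSE]
  }
  pass <- hits[!is.na(hits$coverage) &
                 hits$pident >= params$min_identity - eps &
                 hits$coverage >= params$min_coverage - eps, ,
               drop = FALSE]
  bac_bins <- function(bac) {
    if (is.data.frame(bac_assignments)) {
      bac_assignments$bin_id[bac_assignments$seq_id == bac]
    } else if (!is.null(bac_assignments[[bac]])) {
      bac_assignments[[bac]]$bin_ids
    } else {
      character(0)
    }
  }
  bins <- character(0)
  if (nrow(pass) > 0) {
    pass <- pass[order(pass$sseqid), , drop = FALSE]
    bins <- unlist(lapply(pass$sseqid, bac_bins), use.names = FALSE)
  }
  ev <- data.frame(bac_id = pass$sseqid, identity = pass$pident,
                   coverage = pass$coverage, stringsAsFactors = FALSE)
  # placements to unanchored BACs carry no BIN: drop them from evidence too
  has_bin <- vapply(ev$bac_id, function(b) length(bac_bins(b)) > 0,
                    logical(1))
  .bin_assignment(unigene_id, bins, ev[has_bin, , drop = FALSE])
}

#' Curate putative precursor hits by expect value
#'
#' Applied only to sites whose aggregate gene annotation is "no": hits at
#' e-value <= `precursor_evalue_cutoff` (inclusive) are retained and mark
#' the site as a precursor candidate.
#'
#' @param hits data.frame of placement hits versus known precursor
#'   sequences (needs an `evalue` column; typically also qseqid = site or
#'   carrier sequence, sseqid = precursor id).
#' @param params a [mapping_params()] object.
#' @return the retained subset of `hits`, original order preserved.
#' @export
curate_precursor_hits <- function(hits, params = mapping_params()) {
  if (nrow(hits) == 0) return(hits)
  keep <- hits$evalue <= params$precursor_evalue_cutoff * (1 + 1e-9)
  hits[keep, , drop = FALSE]
}

#' Assign BINs to every sequence of a run
#'
#' BACs are placed via markers, unigenes via filtered placements; returns a
#' long table suitable for the store.
#'
#' @param bac_ids character vector of BAC ids.
#' @param unigene_ids character vector of unigene ids.
#' @param markers marker table ([read_marker_map()] layout).
#' @param placements BLAST tabular hits with coverage
#'   ([read_blast_tab()] with query lengths).
#' @param params a [mapping_params()] object.
#' @return list with `assignments` (named list of `bin_assignment`) and
#'   `table` (data.frame: seq_id, bin_id, method, evidence).
#' @export
assign_bins_all <- function(bac_ids, unigene_ids, markers, placements,
                            params = mapping_params()) {
  assignments <- list()
  rows <- list()
  for (b in bac_ids) {
    a <- suppressMessages(assign_bac_bins(b, markers))
    assignments[[b]] <- a
    if (length(a$bin_ids) > 0) {
      for (bin in a$bin_ids) {
        ev <- a$evidence[a$evidence$bin_id == bin, , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = b, bin_id = bin, method = "marker",
          evidence = paste(sprintf("%s(%s)", ev$name, ev$map_name),
                           collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  for (u in unigene_ids) {
    a <- place_unigene(u, placements, assignments, params)
    assignments[[u]] <- a
    if (length(a$bin_ids) > 0) {
      for (bin in a$bin_ids) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = u, bin_id = bin, method = "blast_placement",
          evidence = paste(sprintf("%s(%.1f%%/%.1f%%)", a$evidence$bac_id,
                                   a$evidence$identity,
                                   a$evidence$coverage), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(seq_id = character(), bin_id = character(),
               method = character(), evidence = character(),
               stringsAsFactors = FALSE)
  }
  list(assignments = assignments, table = tab)
}
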