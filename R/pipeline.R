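# End-to-end pipeline: read inputs, scan, score, curate, annotate, map
# BINs, curate precursor hits, build the relational store, report counts.
# Stage outputs are plain TSV so any stage can be re-run standalone.

#' Assemble a pipeline run configuration
#'
#' Defaults reproduce the published parameter values exactly (scoring
#' penalties 0.5/2.0/1.5/1.0, 20-nt window, threshold <3; placement
#' thresholds 90%/95%; precursor cutoff 1e-50).
#'
#' @param mirnas_fasta,bacs_fasta,unigenes_fasta input FASTA paths (BAC
#'   and unigene FASTAs are each optional, but at least one is required).
#' @param gff3 gene-model + marker GFF3 (optional).
#' @param marker_map marker->BIN TSV (optional; merged with GFF3 markers).
#' @param placements 12-column BLAST tabular of unigene->BAC hits
#'   (optional).
#' @param qtl QTL trait table (optional).
#' @param expression expression matrix TSV (optional).
#' @param precursor_hits TSV of megablast hits vs known precursors, with
#'   columns target_id, start, end, precursor_id, evalue (optional).
#' @param out_dir output directory for stage TSVs and the store.
#' @param scan_params,scoring_params,mapping_params parameter objects.
#' @param seed integer recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(mirnas_fasta, bacs_fasta = NULL,
                       unigenes_fasta = NULL, gff3 = NULL,
                       marker_map = NULL, placements = NULL, qtl = NULL,
                       expression = NULL, precursor_hits = NULL,
                       out_dir = tempfile("binmir_run"),
                       scan_params = binmiR::scan_params(),
                       scoring_params = binmiR::scoring_params(),
                       mapping_params = binmiR::mapping_params(),
                       seed = 1L) {
  cfg <- list(mirnas_fasta = mirnas_fasta, bacs_fasta = bacs_fasta,
              unigenes_fasta = unigenes_fasta, gff3 = gff3,
              marker_map = marker_map, placements = placements,
              qtl = qtl, expression = expression,
              precursor_hits = precursor_hits, out_dir = out_dir,
              scan_params = scan_params, scoring_params = scoring_params,
              mapping_params = mapping_params, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a flat YAML file
#'
#' Recognised keys match the arguments of [run_config()]; parameter
#' overrides are nested maps (`scoring: {threshold: 3.0, ...}`).
#'
#' @param path YAML file.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the yaml package", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  sp <- do.call(scan_params, y$scan %||% list())
  sc <- do.call(scoring_params, y$scoring %||% list())
  mp <- do.call(mapping_params, y$mapping %||% list())
  run_config(mirnas_fasta = y$mirnas_fasta, bacs_fasta = y$bacs_fasta,
             unigenes_fasta = y$unigenes_fasta, gff3 = y$gff3,
             marker_map = y$marker_map, placements = y$placements,
             qtl = y$qtl, expression = y$expression,
             precursor_hits = y$precursor_hits,
             out_dir = y$out_dir %||% tempfile("binmir_run"),
             scan_params = sp, scoring_params = sc, mapping_params = mp,
             seed = y$seed %||% 1L)
}

.require_input <- function(path, what) {
  if (!is.null(path) && !file.exists(path)) {
    stop(structure(list(message = sprintf("missing input file (%s): %s",
                                          what, path),
                        call = NULL),
                   class = c("binmir_missing_input", "error",
                             "condition")))
  }
}

#' Run the full pipeline
#'
#' Stages, in order: read inputs; scan miRNAs against every target; score
#' and curate sites at the strict threshold; annotate curated sites
#' against gene models; place BACs (markers) and unigenes (filtered
#' placements) on BINs; curate precursor hits for gene-negative sites;
#' build the SQLite store; write stage TSVs and a JSON run report.
#'
#' @param config a [run_config()].
#' @return list with `store` (path), `report` (named counts), `sites`
#'   (curated sites data.frame with annotations and BINs), `paths` (stage
#'   outputs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (nm in c("mirnas_fasta", "bacs_fasta", "unigenes_fasta", "gff3",
               "marker_map", "placements", "qtl", "expression",
               "precursor_hits")) {
    .require_input(config[[nm]], nm)
  }
  if (is.null(config$bacs_fasta) && is.null(config$unigenes_fasta)) {
    stop("at least one of bacs_fasta / unigenes_fasta is required",
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  mirnas <- read_mirna_fasta(config$mirnas_fasta)
  targets <- NULL
  if (!is.null(config$bacs_fasta)) {
    targets <- rbind(targets, read_target_fasta(config$bacs_fasta, "BAC"))
  }
  if (!is.null(config$unigenes_fasta)) {
    targets <- rbind(targets,
                     read_target_fasta(config$unigenes_fasta, "UNIGENE"))
  }

  gffd <- if (!is.null(config$gff3)) {
    read_gff3_features(config$gff3)
  } else {
    list(genes = data.frame(seq_id = character(), source = character(),
                            start = integer(), end = integer(),
                            strand = character(),
                            hit_definition = character(),
                            stringsAsFactors = FALSE),
         markers = NULL)
  }
  markers <- gffd$markers
  if (!is.null(config$marker_map)) {
    mm <- read_marker_map(config$marker_map)
    markers <- unique(rbind(markers[, names(mm)], mm))
  }
  if (is.null(markers)) {
    markers <- data.frame(name = character(), map_name = character(),
                          seq_id = character(), position = integer(),
                          bin_id = character(), stringsAsFactors = FALSE)
  }

  # 1. scan + score
  scanned <- scan_all(mirnas, targets, config$scan_params)
  n_candidates <- nrow(scanned$sites)
  utils::write.table(scanned$sites, out("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # 2. curate
  curated <- curate(scanned$sites, config$scoring_params)
  alns <- scanned$alignments[curated$site_id]
  utils::write.table(curated, out("curated_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # 3. annotate
  ann <- annotate_sites(curated, gffd$genes)

  # 4. BIN placement
  ql <- stats::setNames(targets$length, targets$id)
  placements <- if (!is.null(config$placements)) {
    read_blast_tab(config$placements, query_lengths = ql)
  } else {
    read_blast_tab(tempfile_empty())
  }
  bac_ids <- targets$id[targets$kind == "BAC"]
  uni_ids <- targets$id[targets$kind == "UNIGENE"]
  bins <- assign_bins_all(bac_ids, uni_ids, markers, placements,
                          config$mapping_params)
  utils::write.table(bins$table, out("bin_assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # site-level BIN inheritance (sites inherit their carrier's BINs)
  site_bins <- vapply(curated$target_id, function(tid) {
    a <- bins$assignments[[tid]]
    if (is.null(a) || length(a$bin_ids) == 0) "" else
      paste(a$bin_ids, collapse = ",")
  }, character(1))
  curated$bins <- unname(site_bins)

  # 5. precursor curation for gene-negative sites
  prec_tab <- data.frame(site_id = character(), precursor_id = character(),
                         evalue = numeric(), retained = logical(),
                         stringsAsFactors = FALSE)
  ann$precursor_candidate <- FALSE
  if (!is.null(config$precursor_hits)) {
    ph <- utils::read.delim(config$precursor_hits,
                            stringsAsFactors = FALSE)
    rows <- list()
    neg <- ann$site_id[!ann$gene_hit]
    for (sid in neg) {
      s <- curated[curated$site_id == sid, ]
      hit <- ph[ph$target_id == s$target_id & ph$start <= s$end &
                  ph$end >= s$start, , drop = FALSE]
      if (nrow(hit) == 0) next
      kept <- curate_precursor_hits(hit, config$mapping_params)
      if (nrow(kept) > 0) {
        ann$precursor_candidate[ann$site_id == sid] <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sid, precursor_id = hit$precursor_id,
        evalue = hit$evalue,
        retained = hit$evalue <= config$mapping_params$precursor_evalue_cutoff * (1 + 1e-9),
        stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) prec_tab <- do.call(rbind, rows)
  }
  utils::write.table(ann, out("annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # 6. auxiliary tables
  qtl <- if (!is.null(config$qtl)) read_qtl_table(config$qtl) else NULL
  expr <- if (!is.null(config$expression)) {
    read_expression(config$expression)
  } else {
    NULL
  }

  # 7. store
  store_path <- out("binmir.sqlite")
  build_store(
    list(mirnas = mirnas, targets = targets[, c("id", "kind", "length")],
         sites = curated[, c("site_id", "mirna_id", "target_id",
                             "target_kind", "strand", "start", "end",
                             "score")],
         alignments = alns, annotations = ann,
         gene_features = gffd$genes, markers = markers,
         bin_table = bins$table, qtl = qtl, expression = expr,
         precursor_hits = prec_tab),
    store_path,
    provenance = c(seed = as.character(config$seed),
                   threshold = format(config$scoring_params$threshold),
                   min_identity = format(config$mapping_params$min_identity),
                   min_coverage = format(config$mapping_params$min_coverage),
                   precursor_evalue_cutoff =
                     format(config$mapping_params$precursor_evalue_cutoff),
                   run_time = format(Sys.time(), tz = "UTC")),
    params = config$scoring_params)

  report <- c(candidates = n_candidates, curated = nrow(curated),
              annotated_yes = sum(ann$gene_hit),
              annotated_no = sum(!ann$gene_hit),
              precursor_candidates = sum(ann$precursor_candidate),
              mapped_sequences = length(unique(bins$table$seq_id)),
              mapped_sites = sum(nzchar(curated$bins)),
              colocated_qtl = if (is.null(qtl)) 0L else {
                sum(qtl$bin_id %in% unique(unlist(
                  strsplit(curated$bins[nzchar(curated$bins)], ","))))
              })
  jsonlite::write_json(as.list(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(store = store_path, report = report, sites = curated,
       annotations = ann, paths = c(
         candidates = out("candidates.tsv"),
         curated = out("curated_sites.tsv"),
         annotations = out("annotations.tsv"),
         bin_assignments = out("bin_assignments.tsv"),
         report = out("report.json"), store = store_path))
}

tempfile_empty <- function() {
  f <- tempfile(fileext = ".tsv")
  file.create(f)
  f
}
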