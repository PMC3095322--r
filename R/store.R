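# Relational persistence: a 16-table SQLite store joining curated sites
# with annotations, BIN assignments, QTL and expression, plus the query
# surface (by BIN / miRNA / target / keyword) and CSV/HTML export.

.store_tables <- c("species", "mirnas", "sequences", "bacs", "unigenes",
                   "sites", "alignments", "annotations", "gene_features",
                   "markers", "bins", "bin_assignments", "qtl",
                   "expression", "precursor_hits", "provenance")

#' Schema DDL of the relational store
#'
#' The 16-table relational layout is this package's own design (see
#' README). Coordinates are
#' 1-based inclusive throughout; expression is stored long-format so the
#' stage set is not baked into the schema.
#'
#' @return named character vector of CREATE TABLE statements, one per
#'   table, in creation order.
#' @export
store_schema <- function() {
  flags <- paste(sprintf("hit_%s INTEGER NOT NULL",
                         tolower(annotation_channels())), collapse = ", ")
  c(
    species = "CREATE TABLE species (species_id TEXT PRIMARY KEY, name TEXT)",
    mirnas = "CREATE TABLE mirnas (mirna_id TEXT PRIMARY KEY, species_id TEXT REFERENCES species(species_id), sequence TEXT NOT NULL, length INTEGER NOT NULL)",
    sequences = "CREATE TABLE sequences (seq_id TEXT PRIMARY KEY, kind TEXT NOT NULL CHECK (kind IN ('BAC','UNIGENE')), length INTEGER NOT NULL)",
    bacs = "CREATE TABLE bacs (seq_id TEXT PRIMARY KEY REFERENCES sequences(seq_id))",
    unigenes = "CREATE TABLE unigenes (seq_id TEXT PRIMARY KEY REFERENCES sequences(seq_id), description TEXT)",
    sites = "CREATE TABLE sites (site_id TEXT PRIMARY KEY, mirna_id TEXT NOT NULL REFERENCES mirnas(mirna_id), seq_id TEXT NOT NULL REFERENCES sequences(seq_id), strand TEXT NOT NULL CHECK (strand IN ('+','-')), start INTEGER NOT NULL, end INTEGER NOT NULL CHECK (end >= start), score REAL NOT NULL)",
    alignments = "CREATE TABLE alignments (site_id TEXT PRIMARY KEY REFERENCES sites(site_id), alignment_text TEXT NOT NULL)",
    annotations = sprintf("CREATE TABLE annotations (site_id TEXT PRIMARY KEY REFERENCES sites(site_id), %s, gene_hit INTEGER NOT NULL, hit_definition TEXT, precursor_candidate INTEGER NOT NULL DEFAULT 0)", flags),
    gene_features = "CREATE TABLE gene_features (feature_id INTEGER PRIMARY KEY, seq_id TEXT NOT NULL REFERENCES sequences(seq_id), source TEXT NOT NULL, start INTEGER NOT NULL, end INTEGER NOT NULL, strand TEXT, hit_definition TEXT)",
    markers = "CREATE TABLE markers (name TEXT NOT NULL, map_name TEXT NOT NULL, seq_id TEXT REFERENCES sequences(seq_id), position INTEGER, bin_id TEXT REFERENCES bins(bin_id), PRIMARY KEY (name, map_name))",
    bins = "CREATE TABLE bins (bin_id TEXT PRIMARY KEY, chromosome TEXT, segment TEXT)",
    bin_assignments = "CREATE TABLE bin_assignments (seq_id TEXT NOT NULL REFERENCES sequences(seq_id), bin_id TEXT NOT NULL REFERENCES bins(bin_id), method TEXT NOT NULL, evidence TEXT, PRIMARY KEY (seq_id, bin_id, method))",
    qtl = "CREATE TABLE qtl (qtl_id INTEGER PRIMARY KEY, trait TEXT NOT NULL, qtl_type TEXT NOT NULL CHECK (qtl_type IN ('QML','YAL')), bin_id TEXT NOT NULL REFERENCES bins(bin_id), direction TEXT, magnitude REAL, significant INTEGER)",
    expression = "CREATE TABLE expression (unigene_id TEXT NOT NULL REFERENCES sequences(seq_id), stage TEXT NOT NULL, stage_index INTEGER NOT NULL, value REAL, PRIMARY KEY (unigene_id, stage))",
    precursor_hits = "CREATE TABLE precursor_hits (site_id TEXT NOT NULL REFERENCES sites(site_id), precursor_id TEXT NOT NULL, evalue REAL NOT NULL, retained INTEGER NOT NULL, PRIMARY KEY (site_id, precursor_id))",
    provenance = "CREATE TABLE provenance (key TEXT PRIMARY KEY, value TEXT)"
  )
}

.fk_check <- function(child, child_col, parent_keys, what) {
  vals <- child[[child_col]]
  vals <- vals[!is.na(vals)]
  bad <- setdiff(unique(vals), parent_keys)
  if (length(bad) > 0) {
    stop(sprintf("store build aborted: %s reference unknown %s: %s",
                 what, child_col, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
}

#' Build the relational store
#'
#' Validates every foreign key, then writes all 16 tables in a fixed order
#' with stable row ordering so rebuilds from identical inputs are
#' identical except for the provenance table (which carries run metadata).
#'
#' @param inputs list with components `mirnas`, `targets` (id/kind/length),
#'   `sites` (curated only), `alignments` (named list of
#'   `duplex_alignment`), `annotations`, `gene_features`, `markers`,
#'   `bin_table` (seq_id, bin_id, method, evidence), `qtl`, `expression`,
#'   `precursor_hits` (site_id, precursor_id, evalue, retained). Missing
#'   optional components become empty tables.
#' @param path output SQLite file (overwritten).
#' @param provenance named character vector of run metadata.
#' @param params a [scoring_params()] object; persisted sites must respect
#'   its threshold.
#' @return `path`, invisibly.
#' @export
build_store <- function(inputs, path, provenance = character(0),
                        params = scoring_params()) {
  grab <- function(nm, cols) {
    x <- inputs[[nm]]
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
      x <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(cols)), cols),
        stringsAsFactors = FALSE)
    }
    x
  }
  mirnas <- grab("mirnas", c("id", "species", "sequence", "length"))
  targets <- grab("targets", c("id", "kind", "length"))
  sites <- grab("sites", c("site_id", "mirna_id", "target_id",
                           "target_kind", "strand", "start", "end",
                           "score"))
  ann <- inputs$annotations
  gf <- grab("gene_features", c("seq_id", "source", "start", "end",
                                "strand", "hit_definition"))
  markers <- grab("markers", c("name", "map_name", "seq_id", "position",
                               "bin_id"))
  bin_tab <- grab("bin_table", c("seq_id", "bin_id", "method", "evidence"))
  qtl <- grab("qtl", c("trait", "qtl_type", "bin_id", "direction",
                       "magnitude", "significant"))
  expr <- grab("expression", c("unigene_id", "stage", "stage_index",
                               "value"))
  prec <- grab("precursor_hits", c("site_id", "precursor_id", "evalue",
                                   "retained"))

  if (nrow(sites) > 0 &&
      any(sites$score >= params$threshold - .score_eps)) {
    stop("store build aborted: only curated sites (score < threshold) may be persisted",
         call. = FALSE)
  }
  .fk_check(sites, "mirna_id", mirnas$id, "site(s)")
  .fk_check(sites, "target_id", targets$id, "site(s)")
  bin_ids <- sort(unique(c(markers$bin_id, bin_tab$bin_id, qtl$bin_id)))
  bin_ids <- bin_ids[!is.na(bin_ids) & nzchar(bin_ids)]
  .fk_check(bin_tab, "seq_id", targets$id, "bin assignment(s)")
  .fk_check(expr, "unigene_id", targets$id, "expression profile(s)")
  .fk_check(prec, "site_id", sites$site_id, "precursor hit(s)")
  if (!is.null(ann) && nrow(ann) > 0) {
    .fk_check(ann, "site_id", sites$site_id, "annotation(s)")
  }

  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  for (tb in DBI::dbListTables(con)) DBI::dbRemoveTable(con, tb)
  for (ddl in store_schema()) DBI::dbExecute(con, ddl)

  app <- function(tb, df) {
    if (nrow(df) > 0) DBI::dbAppendTable(con, tb, df)
  }
  sp <- sort(unique(mirnas$species[!is.na(mirnas$species)]))
  app("species", data.frame(species_id = sp, name = sp,
                            stringsAsFactors = FALSE))
  mo <- mirnas[order(mirnas$id), , drop = FALSE]
  app("mirnas", data.frame(mirna_id = mo$id, species_id = mo$species,
                           sequence = mo$sequence, length = mo$length,
                           stringsAsFactors = FALSE))
  tg <- targets[order(targets$id), , drop = FALSE]
  app("sequences", data.frame(seq_id = tg$id, kind = tg$kind,
                              length = tg$length, stringsAsFactors = FALSE))
  app("bacs", data.frame(seq_id = tg$id[tg$kind == "BAC"],
                         stringsAsFactors = FALSE))
  uni_ids <- tg$id[tg$kind == "UNIGENE"]
  app("unigenes", data.frame(seq_id = uni_ids,
                             description = rep(NA_character_,
                                               length(uni_ids)),
                             stringsAsFactors = FALSE))
  so <- sites[order(sites$site_id), , drop = FALSE]
  app("sites", data.frame(site_id = so$site_id, mirna_id = so$mirna_id,
                          seq_id = so$target_id, strand = so$strand,
                          start = so$start, end = so$end, score = so$score,
                          stringsAsFactors = FALSE))
  aln <- inputs$alignments
  if (!is.null(aln) && length(aln) > 0) {
    ids <- sort(intersect(names(aln), so$site_id))
    app("alignments", data.frame(
      site_id = ids,
      alignment_text = vapply(aln[ids], render_alignment, character(1)),
      stringsAsFactors = FALSE))
  }
  if (!is.null(ann) && nrow(ann) > 0) {
    an <- ann[order(ann$site_id), , drop = FALSE]
    an <- an[an$site_id %in% so$site_id, , drop = FALSE]
    df <- data.frame(site_id = an$site_id, stringsAsFactors = FALSE)
    for (fc in paste0("hit_", tolower(annotation_channels()))) {
      df[[fc]] <- as.integer(an[[fc]])
    }
    df$gene_hit <- as.integer(an$gene_hit)
    df$hit_definition <- an$hit_definition
    df$precursor_candidate <-
      if ("precursor_candidate" %in% names(an)) {
        as.integer(an$precursor_candidate)
      } else {
        0L
      }
    app("annotations", df)
  }
  if (nrow(gf) > 0) {
    g <- gf[order(gf$seq_id, gf$start, gf$source), , drop = FALSE]
    app("gene_features", data.frame(
      feature_id = seq_len(nrow(g)), seq_id = g$seq_id, source = g$source,
      start = g$start, end = g$end, strand = g$strand,
      hit_definition = g$hit_definition, stringsAsFactors = FALSE))
  }
  app("bins", data.frame(bin_id = bin_ids,
                         chromosome = sub("[A-Z]+$", "", bin_ids),
                         segment = sub("^[0-9]+", "", bin_ids),
                         stringsAsFactors = FALSE))
  mk <- markers[order(markers$name, markers$map_name), , drop = FALSE]
  app("markers", mk)
  bt <- bin_tab[order(bin_tab$seq_id, bin_tab$bin_id, bin_tab$method), ,
                drop = FALSE]
  app("bin_assignments", bt)
  if (nrow(qtl) > 0) {
    q <- qtl[order(qtl$bin_id, qtl$qtl_type, qtl$trait), , drop = FALSE]
    app("qtl", data.frame(qtl_id = seq_len(nrow(q)), trait = q$trait,
                          qtl_type = q$qtl_type, bin_id = q$bin_id,
                          direction = q$direction, magnitude = q$magnitude,
                          significant = as.integer(q$significant),
                          stringsAsFactors = FALSE))
  }
  ex <- expr[order(expr$unigene_id, expr$stage_index), , drop = FALSE]
  app("expression", ex)
  pr <- prec[order(prec$site_id, prec$precursor_id), , drop = FALSE]
  if (nrow(pr) > 0) {
    pr$retained <- as.integer(pr$retained)
    app("precursor_hits", pr)
  }
  if (length(provenance) > 0) {
    app("provenance", data.frame(key = names(provenance),
                                 value = unname(provenance),
                                 stringsAsFactors = FALSE))
  }
  invisible(path)
}

.query_base_sql <- "
SELECT s.site_id, s.mirna_id, s.seq_id AS target_id, sq.kind AS target_kind,
       s.strand, s.start, s.end, s.score,
       ba.bin_id, a.hit_definition, a.gene_hit, a.precursor_candidate,
       al.alignment_text,
       q.trait AS qtl_trait, q.qtl_type
FROM sites s
JOIN sequences sq ON sq.seq_id = s.seq_id
LEFT JOIN annotations a ON a.site_id = s.site_id
LEFT JOIN alignments al ON al.site_id = s.site_id
LEFT JOIN bin_assignments ba ON ba.seq_id = s.seq_id
LEFT JOIN qtl q ON q.bin_id = ba.bin_id
"

#' Query the store by BIN, miRNA, target or keyword
#'
#' Returns one row per site x co-located QTL trait (sites without a mapped
#' BIN or without QTL keep a single row with NAs), carrying the four
#' display fields: co-located QTL, target BIN, hit definition and the
#' rendered alignment, plus the target's expression profile (packed as
#' "stage=value;..." ) when available. Keyword search is a case-insensitive
#' substring match over hit definitions and QTL trait text.
#'
#' @param store path to a store built by [build_store()].
#' @param by one of "bin", "mirna", "target", "keyword".
#' @param term search term.
#' @param fields optional character vector selecting output columns.
#' @return data.frame of result rows (zero rows is not an error).
#' @export
query_store <- function(store, by = c("bin", "mirna", "target", "keyword"),
                        term, fields = NULL) {
  by <- tryCatch(match.arg(by), error = function(e) {
    stop(sprintf("unknown query field '%s': use bin, mirna, target or keyword",
                 by[1]), call. = FALSE)
  })
  con <- DBI::dbConnect(RSQLite::SQLite(), store)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  where <- switch(by,
    bin = "WHERE ba.bin_id = ?",
    mirna = "WHERE s.mirna_id = ?",
    target = "WHERE s.seq_id = ?",
    keyword = "WHERE (LOWER(IFNULL(a.hit_definition,'')) LIKE LOWER(?) OR LOWER(IFNULL(q.trait,'')) LIKE LOWER(?))")
  sql <- paste(.query_base_sql, where,
               "ORDER BY s.site_id, q.qtl_type, q.trait")
  par <- if (by == "keyword") {
    pat <- paste0("%", term, "%")
    list(pat, pat)
  } else {
    list(term)
  }
  rows <- DBI::dbGetQuery(con, sql, params = par)
  # pack expression profiles of unigene targets
  expr <- DBI::dbGetQuery(con,
    "SELECT unigene_id, stage, value FROM expression ORDER BY unigene_id, stage_index")
  if (nrow(rows) > 0) {
    packed <- vapply(rows$target_id, function(id) {
      e <- expr[expr$unigene_id == id, , drop = FALSE]
      if (nrow(e) == 0) return(NA_character_)
      paste(sprintf("%s=%s", e$stage, format(e$value, trim = TRUE)),
            collapse = ";")
    }, character(1))
    rows$expression <- unname(packed)
  } else {
    rows$expression <- character(0)
  }
  if (!is.null(fields)) {
    bad <- setdiff(fields, names(rows))
    if (length(bad) > 0) {
      stop(sprintf("unknown output field(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    rows <- rows[, fields, drop = FALSE]
  }
  rows
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export query rows to CSV or HTML
#'
#' CSV output is RFC-4180 style (all text fields double-quoted, CRLF line
#' ends); HTML output is a single static table page. Both are byte-stable
#' for identical input.
#'
#' @param rows data.frame from [query_store()].
#' @param path output file.
#' @param format "csv" or "html".
#' @return `path`, invisibly.
#' @export
export_rows <- function(rows, path, format = c("csv", "html")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop(sprintf("unknown export format '%s': use csv or html", format[1]),
         call. = FALSE)
  })
  if (format == "csv") {
    utils::write.table(rows, path, sep = ",", eol = "\r\n", na = "",
                       row.names = FALSE, qmethod = "double")
  } else {
    esc <- function(v) .html_escape(ifelse(is.na(v), "", as.character(v)))
    head_cells <- paste(sprintf("<th>%s</th>", esc(names(rows))),
                        collapse = "")
    body <- vapply(seq_len(nrow(rows)), function(i) {
      cells <- vapply(names(rows), function(cn) {
        sprintf("<td>%s</td>", esc(rows[[cn]][i]))
      }, character(1))
      paste0("<tr>", paste(cells, collapse = ""), "</tr>")
    }, character(1))
    html <- c("<!DOCTYPE html>",
              "<html><head><meta charset=\"utf-8\"><title>binmiR results</title></head>",
              "<body><table border=\"1\">",
              paste0("<tr>", head_cells, "</tr>"),
              body,
              "</table></body></html>")
    writeLines(html, path)
  }
  invisible(path)
}
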