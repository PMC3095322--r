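# Store construction and query surface, exercised on a small hand-built
# input set (independent of the pipeline).

mini_inputs <- function() withr::with_seed(7, {
  mseq <- rand_rna(21)
  aln1 <- make_duplex(mseq, mirna_id = "sly-miRt1", target_id = "U1")
  aln2 <- make_duplex(mseq, data.frame(pos = 10L, edit = "mismatch"),
                      mirna_id = "sly-miRt1", target_id = "B1")
  sites <- data.frame(
    site_id = c("s1", "s2"), mirna_id = "sly-miRt1",
    target_id = c("U1", "B1"), target_kind = c("UNIGENE", "BAC"),
    strand = "+", start = c(11L, 101L), end = c(31L, 121L),
    score = c(0, 1.0), stringsAsFactors = FALSE)
  features <- data.frame(seq_id = "U1", source = "AUGUSTUS_UNIGENE",
                         start = 1L, end = 500L, strand = "+",
                         hit_definition = "ATP sulfurylase, chloroplastic",
                         stringsAsFactors = FALSE)
  ann <- annotate_sites(sites[, c("site_id", "target_id", "start", "end")],
                        features)
  list(
    mirnas = data.frame(id = "sly-miRt1", species = "sly",
                        sequence = mseq, length = 21L,
                        stringsAsFactors = FALSE),
    targets = data.frame(id = c("U1", "B1"), kind = c("UNIGENE", "BAC"),
                         length = c(500L, 4000L), stringsAsFactors = FALSE),
    sites = sites, alignments = list(s1 = aln1, s2 = aln2),
    annotations = ann, gene_features = features,
    markers = data.frame(name = "TG432", map_name = "EXPEN1992",
                         seq_id = "B1", position = 500L, bin_id = "5B",
                         stringsAsFactors = FALSE),
    bin_table = data.frame(seq_id = c("B1", "U1"), bin_id = "5B",
                           method = c("marker", "blast_placement"),
                           evidence = c("TG432(EXPEN1992)",
                                        "B1(97.0%/96.0%)"),
                           stringsAsFactors = FALSE),
    qtl = data.frame(trait = c("fructose content", "Brix"),
                     qtl_type = c("QML", "YAL"), bin_id = "5B",
                     direction = "+", magnitude = NA_real_,
                     significant = TRUE, stringsAsFactors = FALSE),
    expression = data.frame(unigene_id = "U1",
                            stage = c("MG", "Br"), stage_index = 1:2,
                            value = c(5.2, 7.9), stringsAsFactors = FALSE),
    precursor_hits = data.frame(site_id = character(),
                                precursor_id = character(),
                                evalue = numeric(), retained = logical(),
                                stringsAsFactors = FALSE))
})

store_table <- function(path, tb) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbReadTable(con, tb)
}

test_that("the store holds exactly the 16 schema tables with valid keys", {
  path <- withr::local_tempfile(fileext = ".sqlite")
  build_store(mini_inputs(), path, provenance = c(run = "test"))
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  expect_setequal(DBI::dbListTables(con), names(store_schema()))
  expect_length(DBI::dbListTables(con), 16)
  fk <- DBI::dbGetQuery(con, "PRAGMA foreign_key_check")
  expect_equal(nrow(fk), 0)
  expect_equal(DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM sites")$n, 2)
})

test_that("empty inputs produce a store with 16 empty tables", {
  path <- withr::local_tempfile(fileext = ".sqlite")
  build_store(list(), path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  tabs <- DBI::dbListTables(con)
  expect_length(tabs, 16)
  for (tb in tabs) {
    expect_equal(nrow(DBI::dbReadTable(con, tb)), 0)
  }
})

test_that("dangling references abort the build naming the offender", {
  inp <- mini_inputs()
  inp$sites$mirna_id[2] <- "ghost-miR"
  path <- withr::local_tempfile(fileext = ".sqlite")
  expect_error(build_store(inp, path), "ghost-miR")
  inp2 <- mini_inputs()
  inp2$sites$score[1] <- 3.2   # uncurated site
  expect_error(build_store(inp2, path), "curated")
})

test_that("query by miRNA round-trips exactly the persisted curated sites", {
  path <- withr::local_tempfile(fileext = ".sqlite")
  inp <- mini_inputs()
  build_store(inp, path)
  rows <- query_store(path, by = "mirna", term = "sly-miRt1")
  expect_setequal(unique(rows$site_id), inp$sites$site_id)
  expect_true(all(c("qtl_trait", "bin_id", "hit_definition",
                    "alignment_text", "expression") %in% names(rows)))
  # expression profile travels with the unigene target
  u1 <- rows[rows$target_id == "U1", ]
  expect_true(all(grepl("MG=5.2;Br=7.9", u1$expression)))
})

test_that("query by BIN and by target behave; unknown fields error", {
  path <- withr::local_tempfile(fileext = ".sqlite")
  build_store(mini_inputs(), path)
  expect_setequal(unique(query_store(path, "bin", "5B")$site_id),
                  c("s1", "s2"))
  expect_equal(nrow(query_store(path, "bin", "9Z")), 0)  # empty, no error
  expect_setequal(unique(query_store(path, "target", "U1")$site_id), "s1")
  expect_error(query_store(path, "flavour", "x"), "unknown query field")
  expect_error(query_store(path, "bin", "5B", fields = "nope"),
               "unknown output field")
})

test_that("keyword search is case-insensitive over definitions and traits", {
  path <- withr::local_tempfile(fileext = ".sqlite")
  build_store(mini_inputs(), path)
  lo <- query_store(path, "keyword", "fructose")
  up <- query_store(path, "keyword", "FRUCTOSE")
  expect_identical(lo, up)
  expect_gte(nrow(lo), 1)
  expect_true(all(lo$qtl_trait == "fructose content" |
                    grepl("fructose", lo$hit_definition,
                          ignore.case = TRUE)))
  def <- query_store(path, "keyword", "sulfurylase")
  expect_true(all(grepl("sulfurylase", def$hit_definition,
                        ignore.case = TRUE)))
})

test_that("rebuilding from identical inputs reproduces all data tables", {
  p1 <- withr::local_tempfile(fileext = ".sqlite")
  p2 <- withr::local_tempfile(fileext = ".sqlite")
  build_store(mini_inputs(), p1, provenance = c(run = "a",
                                                time = "2026-01-01"))
  build_store(mini_inputs(), p2, provenance = c(run = "b",
                                                time = "2026-06-30"))
  for (tb in setdiff(names(store_schema()), "provenance")) {
    expect_identical(store_table(p1, tb), store_table(p2, tb))
  }
})

test_that("CSV and HTML exports are quoted, escaped and byte-stable", {
  rows <- data.frame(site_id = c("s1", "s2"),
                     hit_definition = c("kinase, putative",
                                        "a <b> & c"),
                     score = c(0, 1.5), stringsAsFactors = FALSE)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_rows(rows, f1, "csv")
  export_rows(rows, f2, "csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  lines <- readLines(f1)
  expect_length(lines, 3)   # header + 2 rows
  expect_match(lines[2], "\"kinase, putative\"", fixed = TRUE)

  h1 <- withr::local_tempfile(fileext = ".html")
  h2 <- withr::local_tempfile(fileext = ".html")
  export_rows(rows, h1, "html")
  export_rows(rows, h2, "html")
  expect_identical(readLines(h1), readLines(h2))
  expect_true(any(grepl("a &lt;b&gt; &amp; c", readLines(h1))))
  expect_error(export_rows(rows, f1, "xlsx"), "unknown export format")
})
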