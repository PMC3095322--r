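mk_markers <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], map_name = r[[2]], seq_id = r[[3]],
               position = as.integer(r[[4]]), bin_id = r[[5]],
               stringsAsFactors = FALSE)
  }))
}

mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(qseqid = r[[1]], sseqid = r[[2]], pident = r[[3]],
               length = 0L, mismatch = 0L, gapopen = 0L, qstart = 1L,
               qend = 1L, sstart = 1L, send = 1L, evalue = 1e-100,
               bitscore = 100, coverage = r[[4]], stringsAsFactors = FALSE)
  }))
}

test_that("BAC BINs are the union over markers of both maps", {
  mk <- mk_markers(list("TG432", "EXPEN1992", "bac1", 350, "5B"),
                   list("CT53", "EXPEN2000", "bac1", 100, "5B"),
                   list("X1", "EXPEN2000", "bac2", 10, "2A"))
  a <- assign_bac_bins("bac1", mk)
  expect_equal(a$bin_ids, "5B")
  expect_equal(nrow(a$evidence), 2)   # one BIN, two evidence items
  multi <- assign_bac_bins("bac1",
                           rbind(mk, mk_markers(list("Y", "EXPEN1992",
                                                     "bac1", 900, "5C"))))
  expect_equal(multi$bin_ids, c("5B", "5C"))
  expect_message(none <- assign_bac_bins("bacX", mk), "unassigned")
  expect_length(none$bin_ids, 0)
  expect_equal(nrow(none$evidence), 0)
})

test_that("unigene placement thresholds are inclusive at the printed values", {
  bacs <- list(bac1 = assign_bac_bins(
    "bac1", mk_markers(list("TG432", "EXPEN1992", "bac1", 350, "5B"))))
  at_boundary <- place_unigene("u1", mk_hits(list("u1", "bac1", 90.0,
                                                  95.0)), bacs)
  expect_equal(at_boundary$bin_ids, "5B")
  below_id <- place_unigene("u1", mk_hits(list("u1", "bac1", 89.9, 99.0)),
                            bacs)
  expect_length(below_id$bin_ids, 0)
  below_cov <- place_unigene("u1", mk_hits(list("u1", "bac1", 99.0,
                                                94.9)), bacs)
  expect_length(below_cov$bin_ids, 0)
})

test_that("a unigene inherits every BIN of each passing anchored BAC", {
  mk <- mk_markers(list("A", "EXPEN1992", "bac1", 1, "5B"),
                   list("B", "EXPEN2000", "bac1", 2, "5C"),
                   list("C", "EXPEN1992", "bac2", 3, "2A"))
  bacs <- list(bac1 = assign_bac_bins("bac1", mk),
               bac2 = assign_bac_bins("bac2", mk))
  a <- place_unigene("u1", mk_hits(list("u1", "bac1", 95, 99),
                                   list("u1", "bac2", 96, 98)), bacs)
  expect_equal(a$bin_ids, c("2A", "5B", "5C"))
  expect_equal(nrow(a$evidence), 2)
})

test_that("BIN sets are non-empty exactly when evidence is non-empty", {
  bacs <- list()  # the matched BAC is unanchored
  a <- place_unigene("u1", mk_hits(list("u1", "bacZ", 99, 99)), bacs)
  expect_length(a$bin_ids, 0)
  expect_equal(nrow(a$evidence), 0)
})

test_that("relaxing placement thresholds never drops a placement", {
  withr::local_seed(9)
  bacs <- list(bac1 = assign_bac_bins(
    "bac1", mk_markers(list("M", "EXPEN1992", "bac1", 1, "3A"))))
  for (i in 1:20) {
    hits <- mk_hits(list("u1", "bac1", runif(1, 80, 100),
                         runif(1, 85, 100)))
    strict <- place_unigene("u1", hits, bacs, mapping_params())
    relaxed <- place_unigene("u1", hits, bacs,
                             mapping_params(min_identity = 85,
                                            min_coverage = 90))
    expect_true(all(strict$bin_ids %in% relaxed$bin_ids))
  }
})

test_that("precursor curation keeps e-values at or below 1e-50", {
  hits <- data.frame(qseqid = "s", sseqid = c("p1", "p2", "p3"),
                     evalue = c(1e-60, 1e-50, 1e-40))
  kept <- curate_precursor_hits(hits)
  expect_equal(kept$sseqid, c("p1", "p2"))   # boundary inclusive
  expect_equal(nrow(curate_precursor_hits(hits[0, ])), 0)
})

test_that("assign_bins_all builds a store-ready long table", {
  mk <- mk_markers(list("TG432", "EXPEN1992", "bac1", 350, "5B"))
  hits <- mk_hits(list("u1", "bac1", 95, 99), list("u2", "bac1", 80, 99))
  res <- assign_bins_all("bac1", c("u1", "u2"), mk, hits)
  expect_setequal(res$table$seq_id, c("bac1", "u1"))
  expect_true(all(res$table$bin_id == "5B"))
  expect_equal(sort(unique(res$table$method)),
               c("blast_placement", "marker"))
  expect_length(res$assignments[["u2"]]$bin_ids, 0)
})
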