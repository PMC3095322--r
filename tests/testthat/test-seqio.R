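test_that("miRNA FASTA reading normalizes whitespace and T/U", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "UGGAGUGUGA UAGUCCCUUG GCA"), f)
  m <- read_mirna_fasta(f)
  expect_equal(m$id, "x")
  expect_equal(m$length, 23)
  expect_equal(m$sequence, "UGGAGUGUGAUAGUCCCUUGGCA")

  writeLines(c(">y", "TGGAGTGTGATAGTCCCTTGGCA"), f)
  m2 <- read_mirna_fasta(f)
  expect_false(grepl("T", m2$sequence))
  expect_equal(m2$sequence, "UGGAGUGUGAUAGUCCCUUGGCA")
})

test_that("duplicate or malformed miRNA records are rejected", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "UGGAGUGUGAUAGUCCCUUGGCA",
               ">x", "UGGAGUGUGAUAGUCCCUUGGCA"), f)
  expect_error(read_mirna_fasta(f), "duplicate")
  writeLines(c(">z", "UGGAGUGUGAUAGXCCCUUGGCA"), f)
  expect_error(read_mirna_fasta(f), "z")
  writeLines(c(">w", "UGGAG"), f)
  expect_error(read_mirna_fasta(f), "shorter")
  expect_error(read_mirna_fasta(tempfile()), "not found")
})

test_that("species tag parsing and target reading behave", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sly-miR395a", "CUGAAGUGUUUGGGGGAACUC"), f)
  expect_equal(read_mirna_fasta(f)$species, "sly")

  g <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "ACGTACGTACGTACGTACGTACGT", ">tiny", "ACGT"), g)
  expect_warning(tg <- read_target_fasta(g, "UNIGENE"), "tiny")
  expect_equal(tg$id, "t1")
  expect_equal(tg$kind, "UNIGENE")
})

test_that("FASTA round-trip preserves ids and sequences exactly", {
  withr::local_seed(11)
  ids <- sprintf("seq%02d", 1:8)
  seqs <- vapply(sample(30:200, 8), rand_dna, character(1))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ids, seqs, f)
  back <- read_target_fasta(f, "BAC")
  expect_identical(back$id, ids)
  expect_identical(back$sequence, seqs)
})

test_that("T/U normalization is idempotent", {
  withr::local_seed(5)
  x <- c(vapply(rep(30, 10), rand_dna, character(1)),
         vapply(rep(25, 10), rand_rna, character(1)))
  expect_identical(normalize_rna(normalize_rna(x)), normalize_rna(x))
  expect_identical(normalize_dna(normalize_dna(x)), normalize_dna(x))
})

test_that("GFF3 reader separates genes from markers and keeps 1-based coords", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "bac1\tAUGUSTUS_DENOVO\tgene\t100\t400\t.\t+\t.\tID=g1;Note=some kinase",
    "bac1\tSGN_marker\tgenetic_marker\t350\t350\t.\t+\t.\tID=m1;Name=TG432;map=EXPEN1992;bin=5B",
    "bac1\tWEIRD_SOURCE\tgene\t10\t20\t.\t+\t.\tID=g2"), f)
  got <- read_gff3_features(f)
  expect_equal(nrow(got$genes), 1)
  expect_equal(got$genes$start, 100)
  expect_equal(got$genes$end, 400)
  expect_equal(got$genes$source, "AUGUSTUS_DENOVO")
  expect_equal(got$genes$hit_definition, "some kinase")
  expect_equal(got$markers$name, "TG432")
  expect_equal(got$markers$bin_id, "5B")
  expect_equal(got$markers$map_name, "EXPEN1992")
  expect_equal(unname(got$skipped["unknown_source"]), 1L)
})

test_that("GFF3 records with end < start are rejected individually", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "bac1\tGENOMETHREADER\tgene\t500\t100\t.\t+\t.\tID=bad",
    "bac1\tGENOMETHREADER\tgene\t100\t500\t.\t+\t.\tID=ok;Note=fine"), f)
  expect_message(got <- read_gff3_features(f), "rejected 1")
  expect_equal(nrow(got$genes), 1)
  expect_true(all(got$genes$start <= got$genes$end))
  expect_equal(unname(got$skipped["bad_coords"]), 1L)
})

test_that("empty GFF3 gives empty tables without error", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", f)
  got <- read_gff3_features(f)
  expect_equal(nrow(got$genes), 0)
  expect_equal(nrow(got$markers), 0)
  file.create(f2 <- withr::local_tempfile(fileext = ".gff3"))
  got2 <- read_gff3_features(f2)
  expect_equal(nrow(got2$genes), 0)
})

test_that("BLAST tabular reader computes coverage and parses e-values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("q1", "s1", "97.0", "960", "28", "0", "1", "960",
                     "100", "1059", "1e-60", "1700"), collapse = "\t"), f)
  got <- read_blast_tab(f, query_lengths = c(q1 = 1000L))
  expect_equal(got$coverage, 96.0)   # 960 / 1000 x 100
  expect_equal(got$evalue, 1e-60)
  expect_equal(got$pident, 97.0)
})

test_that("BLAST tabular reader enforces 12 columns and allows empty files", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t90.0\t100", f)
  expect_error(read_blast_tab(f), "line 1")
  file.create(f2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_equal(nrow(read_blast_tab(f2)), 0)
})

test_that("marker map and QTL table validation works", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tmap\tbac\tposition\tbin",
               "TG432\tEXPEN1992\tbac1\t350\t5B"), f)
  mm <- read_marker_map(f)
  expect_equal(mm$bin_id, "5B")
  writeLines(c("name\tmap\tbac\tposition\tbin",
               "TG432\tNOTAMAP\tbac1\t350\t5B"), f)
  expect_error(read_marker_map(f), "map")
  writeLines(c("name\tmap\tbac\tposition\tbin",
               "TG432\tEXPEN1992\tbac1\t350\tfive-B"), f)
  expect_error(read_marker_map(f), "BIN")

  q <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("trait\tqtl_type\tbin", "fructose content\tQML\t5B",
               "Brix\tYAL\t5B"), q)
  qt <- read_qtl_table(q)
  expect_equal(qt$qtl_type, c("QML", "YAL"))
  writeLines(c("trait\tqtl_type\tbin", "x\tBAD\t5B"), q)
  expect_error(read_qtl_table(q), "QML or YAL")
})

test_that("expression matrix is returned long with stage order preserved", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("unigene_id\t10DPA\tMG\tBr", "u1\t1.5\t2.5\t3.5"), f)
  ex <- read_expression(f)
  expect_equal(nrow(ex), 3)
  expect_equal(ex$stage, c("10DPA", "MG", "Br"))
  expect_equal(ex$stage_index, 1:3)
  expect_equal(ex$value, c(1.5, 2.5, 3.5))
})
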