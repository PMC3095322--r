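# Seeded synthetic fixture generator.
#
# Produces a complete toy dataset -- miRNAs, BAC/unigene sequences with
# planted target sites, GFF3 gene models and markers, a marker->BIN map,
# QTL and expression tables, plus a machine-readable ground-truth manifest
# -- so every stage and the end-to-end pipeline are testable offline.
#
# The "miR395-like" preset plants three clustered precursor-style loci on
# one BAC between two markers flanking BIN 5B, with 19 QML + 5 YAL rows
# for that BIN, mirroring the proof-of-concept layout used throughout the
# documentation.

.wc_partner <- c(A = "T", C = "G", G = "C", U = "A")
.wobble_partner <- c(G = "T", U = "G")

#' Describe one planted target site
#'
#' @param mirna_id,target_id identifiers within the bundle.
#' @param position plus-strand start coordinate of the planted site.
#' @param strand "+" or "-" ("+" only for unigenes).
#' @param profile data.frame with columns `pos` (miRNA position, 5' end =
#'   1) and `edit` (wobble / mismatch / insertion / deletion); zero rows
#'   for a perfect duplex. An insertion at `pos` places an extra target
#'   base between miRNA positions `pos` and `pos + 1`.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(mirna_id, target_id, position, strand = "+",
                       profile = data.frame(pos = integer(),
                                            edit = character())) {
  stopifnot(strand %in% c("+", "-"),
            all(profile$edit %in% c("wobble", "mismatch", "insertion",
                                    "deletion")))
  out <- list(mirna_id = mirna_id, target_id = target_id,
              position = as.integer(position), strand = strand,
              profile = profile)
  class(out) <- "plant_spec"
  out
}

#' Expected window-minimum score of a mutation profile
#'
#' Independent reference scorer used for manifest ground truth: it works
#' directly on the edit profile (never on an alignment), summing, for each
#' 20-position window, the penalties of the edits it contains -- wobble
#' 0.5, deletion/insertion 2.0, mismatch 1.5 at positions 2-7 else 1.0; an
#' insertion between positions p and p+1 is charged to windows containing
#' both -- and returning the minimum.
#'
#' @param profile edit profile as in [plant_spec()].
#' @param mirna_len miRNA length (>= 20).
#' @param window_len window length (default 20).
#' @return numeric expected score.
#' @export
profile_expected_score <- function(profile, mirna_len, window_len = 20L) {
  stopifnot(mirna_len >= window_len)
  n_win <- mirna_len - window_len + 1L
  win_scores <- vapply(seq_len(n_win), function(w) {
    lo <- w
    hi <- w + window_len - 1L
    total <- 0
    for (k in seq_len(nrow(profile))) {
      p <- profile$pos[k]
      e <- profile$edit[k]
      if (e == "insertion") {
        if (lo <= p && p + 1L <= hi) total <- total + 2.0
      } else if (p >= lo && p <= hi) {
        total <- total + switch(e,
          wobble = 0.5,
          deletion = 2.0,
          mismatch = if (p >= 2 && p <= 7) 1.5 else 1.0)
      }
    }
    total
  }, numeric(1))
  min(win_scores)
}

# target-site bases along miRNA order (P and I columns), given the profile
.site_partner_bases <- function(mirna_seq, profile) {
  m <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  L <- length(m)
  out <- character(0)
  for (i in seq_len(L)) {
    edits <- profile$edit[profile$pos == i]
    if ("deletion" %in% edits) {
      # miRNA base unpaired; no target base
    } else if ("wobble" %in% edits) {
      wp <- .wobble_partner[m[i]]
      if (is.na(wp)) {
        stop(sprintf("wobble edit at position %d needs a G or U miRNA base",
                     i), call. = FALSE)
      }
      out <- c(out, wp)
    } else if ("mismatch" %in% edits) {
      banned <- c(.wc_partner[m[i]], .wobble_partner[m[i]])
      out <- c(out, sample(setdiff(c("A", "C", "G", "T"), banned), 1))
    } else {
      out <- c(out, .wc_partner[m[i]])
    }
    if ("insertion" %in% edits && i < L) {
      # choose a base that pairs with neither flanking miRNA position, so
      # the scanner cannot slide the gap into an equal-scoring alignment
      banned <- c(.wc_partner[m[i]], .wobble_partner[m[i]],
                  .wc_partner[m[i + 1]], .wobble_partner[m[i + 1]])
      pool <- setdiff(c("A", "C", "G", "T"), banned)
      if (length(pool) == 0) pool <- setdiff(c("A", "C", "G", "T"),
                                             c(.wc_partner[m[i]],
                                               .wc_partner[m[i + 1]]))
      out <- c(out, sample(pool, 1))
    }
  }
  out
}

# plus-strand segment carrying the site (see scan-space derivation in
# scan.R): '+' -> reverse of the partner bases, '-' -> their complement
.site_plus_segment <- function(partners, strand) {
  s <- paste(partners, collapse = "")
  if (strand == "+") .reverse_chars(s) else complement_dna(s)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

.preset_qml_traits <- c(
  "fructose content", "glucose content", "sucrose content",
  "citrate content", "malate content", "fumarate content",
  "succinate content", "glutamate content", "aspartate content",
  "alanine content", "valine content", "leucine content",
  "phenylalanine content", "GABA content", "myo-inositol content",
  "glycerate content", "phosphate content", "palmitate content",
  "stearate content")

.preset_yal_traits <- c("fruit length", "plant weight", "Brix",
                        "harvest index", "seeds per plant")

.expr_stages <- c("10DPA", "20DPA", "30DPA", "MG", "Br", "Br5", "Br10")

# deterministic random profile from the "safe" plan space: any number of
# wobbles (on G/U positions) up to 2, plus at most two non-pairing edits so
# every sub-threshold profile also clears the 90% pairing gate
.random_profile <- function(mirna_seq) {
  m <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  L <- length(m)
  gu <- which(m %in% c("G", "U"))
  prof <- data.frame(pos = integer(), edit = character(),
                     stringsAsFactors = FALSE)
  n_wob <- sample(0:min(2, length(gu)), 1)
  if (n_wob > 0) {
    prof <- rbind(prof, data.frame(
      pos = sort(sample(gu, n_wob)), edit = "wobble",
      stringsAsFactors = FALSE))
  }
  extra <- sample(c("none", "mismatch", "insertion", "deletion"), 1,
                  prob = c(0.4, 0.3, 0.15, 0.15))
  if (extra != "none") {
    # keep indels clear of the window boundaries so a gap cannot drift
    # across them into an equivalent alignment with a different score
    range_of <- if (extra == "mismatch") seq_len(L) else 3:(L - 3)
    free <- setdiff(range_of, prof$pos)
    prof <- rbind(prof, data.frame(pos = sample(free, 1), edit = extra,
                                   stringsAsFactors = FALSE))
  }
  prof[order(prof$pos), , drop = FALSE]
}

.profile_string <- function(profile) {
  if (nrow(profile) == 0) return("perfect")
  paste(sprintf("%d:%s", profile$pos, profile$edit), collapse = ",")
}

#' Generate a complete synthetic fixture bundle
#'
#' Writes FASTA/GFF3/TSV inputs plus a JSON ground-truth manifest to
#' `out_dir` and returns everything in memory. Identical seeds give
#' identical bundles. Background sequence is random with complementarity
#' to the planted miRNAs suppressed: after planting, every target is
#' scanned exhaustively over all loci and strands with the packaged
#' scanner, and any background giving a spurious sub-threshold site (or
#' disturbing a planted one) is resampled.
#'
#' @param seed integer seed (mandatory; all randomness derives from it).
#' @param out_dir output directory (created if needed); NULL to skip
#'   writing files.
#' @param n_mirnas total miRNAs, >= 5 (the first five carry the preset
#'   plant plan; extras get one random safe-profile site each).
#' @param n_bacs number of BACs, >= 3.
#' @param n_unigenes number of unigenes, >= 6.
#' @param max_regen resampling attempts per target before giving up.
#' @param verify run the internal scan check (TRUE; turning it off is only
#'   sensible when profiling).
#' @return list with `mirnas`, `targets`, `gene_features`, `markers`,
#'   `qtl`, `expression`, `placements`, `precursor_hits`, `manifest`
#'   (planted-site truth data.frame), `paths` (named file paths or NULL).
#' @export
simulate_bundle <- function(seed, out_dir = NULL, n_mirnas = 6L,
                            n_bacs = 3L, n_unigenes = 6L,
                            max_regen = 10L, verify = TRUE) {
  stopifnot(n_mirnas >= 5, n_bacs >= 3, n_unigenes >= 6)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  # ---- miRNAs: five preset + extras ------------------------------------
  mir_seqs <- c(
    "sly-simR395a" = "UGGAGUGUGUCAGUCACGAAG",   # 21 nt, pos 10 = U
    "sly-simR102"  = "ACGUACGAUCCAGCUAAGGAC",   # 21 nt, pos 18 = G
    "ath-simR203"  = .random_rna(22),
    "sly-simR244"  = .random_rna(24),
    "ath-simR305"  = .random_rna(21))
  extra_n <- n_mirnas - 5L
  if (extra_n > 0) {
    ex <- vapply(seq_len(extra_n), function(i) .random_rna(sample(20:24, 1)),
                 character(1))
    names(ex) <- sprintf("sly-simR9%02d", seq_len(extra_n))
    mir_seqs <- c(mir_seqs, ex)
  }
  mirnas <- data.frame(id = names(mir_seqs),
                       species = sub("-.*$", "", names(mir_seqs)),
                       sequence = unname(mir_seqs),
                       length = nchar(unname(mir_seqs)),
                       stringsAsFactors = FALSE)

  # ---- targets ---------------------------------------------------------
  bac_ids <- sprintf("SIMBAC%03d", seq_len(n_bacs))
  bac_lens <- c(6000L, 4000L, rep(3000L, n_bacs - 2L))
  uni_ids <- sprintf("SIM-U3%03d", seq_len(n_unigenes))
  uni_lens <- rep(800L, n_unigenes)

  # ---- plant plan ------------------------------------------------------
  mk_prof <- function(pos, edit) {
    data.frame(pos = as.integer(pos), edit = edit, stringsAsFactors = FALSE)
  }
  empty_prof <- mk_prof(integer(0), character(0))
  plan <- list(
    plant_spec("sly-simR395a", uni_ids[1], 301L, "+",
               mk_prof(10, "wobble")),                       # 0.5
    plant_spec("sly-simR395a", uni_ids[2], 421L, "+",
               mk_prof(4, "mismatch")),                      # 1.5
    plant_spec("sly-simR395a", bac_ids[1], 2001L, "+", empty_prof),  # 0
    plant_spec("sly-simR395a", bac_ids[1], 2301L, "-",
               mk_prof(12, "mismatch")),                     # 1.0
    plant_spec("sly-simR395a", bac_ids[1], 2601L, "+",
               mk_prof(c(10, 15), c("wobble", "deletion"))), # 2.5
    plant_spec("sly-simR102", uni_ids[3], 201L, "+",
               mk_prof(c(4, 12, 18),
                       c("mismatch", "mismatch", "wobble"))), # 3.0 (out)
    plant_spec("sly-simR102", uni_ids[4], 351L, "+",
               mk_prof(c(3, 5, 18),
                       c("mismatch", "mismatch", "wobble"))), # 3.5 (out)
    plant_spec("ath-simR203", bac_ids[2], 801L, "+", empty_prof),    # 0
    plant_spec("sly-simR244", uni_ids[5], 501L, "+",
               mk_prof(22, "mismatch")))                     # 0 (window)
  if (extra_n > 0) {
    for (i in seq_len(extra_n)) {
      mid <- sprintf("sly-simR9%02d", i)
      tid <- uni_ids[6]
      plan[[length(plan) + 1L]] <- plant_spec(
        mid, tid, as.integer(100 + (i - 1) * 120), "+",
        .random_profile(mir_seqs[[mid]]))
    }
  }

  # ---- realize planted segments ---------------------------------------
  planted <- lapply(plan, function(ps) {
    partners <- .site_partner_bases(mir_seqs[[ps$mirna_id]], ps$profile)
    seg <- .site_plus_segment(partners, ps$strand)
    L <- nchar(mir_seqs[[ps$mirna_id]])
    score <- profile_expected_score(ps$profile, L)
    list(spec = ps, segment = seg, start = ps$position,
         end = ps$position + nchar(seg) - 1L, expected_score = score,
         curated = score < 3 - 1e-9)
  })

  tgt_ids <- c(bac_ids, uni_ids)
  tgt_kind <- c(rep("BAC", n_bacs), rep("UNIGENE", n_unigenes))
  tgt_len <- c(bac_lens, uni_lens)
  names(tgt_len) <- tgt_ids

  planted_by_tgt <- split(planted,
                          vapply(planted, function(p) p$spec$target_id,
                                 character(1)))
  for (ps in planted) {
    if (ps$end > tgt_len[[ps$spec$target_id]]) {
      stop(sprintf("plant position out of bounds on %s",
                   ps$spec$target_id), call. = FALSE)
    }
  }

  build_target <- function(id) {
    n <- tgt_len[[id]]
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    for (p in planted_by_tgt[[id]] %||% list()) {
      bases[p$start:p$end] <- strsplit(p$segment, "", fixed = TRUE)[[1]]
    }
    paste(bases, collapse = "")
  }
  resample_background <- function(seqstr, id) {
    n <- nchar(seqstr)
    bases <- strsplit(seqstr, "", fixed = TRUE)[[1]]
    keep <- rep(FALSE, n)
    for (p in planted_by_tgt[[id]] %||% list()) {
      keep[p$start:p$end] <- TRUE
    }
    bases[!keep] <- sample(c("A", "C", "G", "T"), sum(!keep),
                           replace = TRUE)
    paste(bases, collapse = "")
  }

  targets <- data.frame(id = tgt_ids, kind = tgt_kind,
                        sequence = vapply(tgt_ids, build_target,
                                          character(1)),
                        length = unname(tgt_len), stringsAsFactors = FALSE)

  # ---- internal suppression / recovery check ---------------------------
  if (verify) {
    sp <- scan_params()
    for (j in seq_len(nrow(targets))) {
      ok <- FALSE
      for (try in seq_len(max_regen)) {
        found <- scan_all(mirnas, targets[j, , drop = FALSE], sp)
        cur <- curate(found$sites)
        exp_sites <- planted_by_tgt[[targets$id[j]]] %||% list()
        exp_cur <- Filter(function(p) p$curated, exp_sites)
        key <- function(m, s, st, e, sc) {
          paste(m, s, st, e, sprintf("%.3f", sc), sep = "|")
        }
        got <- sort(key(cur$mirna_id, cur$strand, cur$start, cur$end,
                        cur$score))
        want <- sort(vapply(exp_cur, function(p) {
          key(p$spec$mirna_id, p$spec$strand, p$start, p$end,
              p$expected_score)
        }, character(1)))
        if (identical(got, want)) {
          ok <- TRUE
          break
        }
        targets$sequence[j] <- resample_background(targets$sequence[j],
                                                   targets$id[j])
      }
      if (!ok) {
        stop(sprintf("fixture generation failed for %s: background could not be de-complemented in %d attempts",
                     targets$id[j], max_regen), call. = FALSE)
      }
    }
  }

  # ---- gene features ---------------------------------------------------
  gene_features <- rbind(
    data.frame(seq_id = bac_ids[1], source = "GENOMETHREADER",
               start = 101L, end = 901L, strand = "+",
               hit_definition = "hypothetical protein, chr5 long arm",
               stringsAsFactors = FALSE),
    data.frame(seq_id = bac_ids[1], source = "AUGUSTUS_TOMATO_EST",
               start = 4001L, end = 4801L, strand = "-",
               hit_definition = "sulfate transporter-like protein",
               stringsAsFactors = FALSE),
    data.frame(seq_id = bac_ids[2], source = "AUGUSTUS_DENOVO",
               start = 501L, end = 1501L, strand = "+",
               hit_definition = "MYB transcription factor-like",
               stringsAsFactors = FALSE),
    data.frame(seq_id = bac_ids[2], source = "BLASTX_ARATH",
               start = 601L, end = 1401L, strand = "+",
               hit_definition = "AT-homolog: R2R3 MYB domain protein",
               stringsAsFactors = FALSE),
    data.frame(seq_id = bac_ids[3], source = "AUGUSTUS_POTATO_EST",
               start = 201L, end = 1001L, strand = "+",
               hit_definition = "cytochrome P450-like",
               stringsAsFactors = FALSE),
    data.frame(seq_id = uni_ids[1], source = "AUGUSTUS_UNIGENE",
               start = 1L, end = uni_lens[1], strand = "+",
               hit_definition = "ATP sulfurylase (APS)-like",
               stringsAsFactors = FALSE),
    data.frame(seq_id = uni_ids[2], source = "BLASTX_ARATH",
               start = 1L, end = uni_lens[2], strand = "+",
               hit_definition = "sulfate adenylyltransferase",
               stringsAsFactors = FALSE),
    data.frame(seq_id = uni_ids[3], source = "AUGUSTUS_UNIGENE",
               start = 1L, end = uni_lens[3], strand = "+",
               hit_definition = "protein kinase-like",
               stringsAsFactors = FALSE),
    data.frame(seq_id = uni_ids[5], source = "AUGUSTUS_UNIGENE",
               start = 1L, end = uni_lens[5], strand = "+",
               hit_definition = "pectinesterase-like",
               stringsAsFactors = FALSE),
    data.frame(seq_id = uni_ids[6], source = "AUGUSTUS_UNIGENE",
               start = 1L, end = uni_lens[6], strand = "+",
               hit_definition = "unknown expressed protein",
               stringsAsFactors = FALSE))

  # ---- markers and BIN map --------------------------------------------
  markers <- data.frame(
    name = c("CT53", "CT53", "TG432", "SIM-M201"),
    map_name = c("EXPEN2000", "EXPEN1992", "EXPEN1992", "EXPEN2000"),
    seq_id = c(bac_ids[1], bac_ids[1], bac_ids[1], bac_ids[2]),
    position = c(1500L, 1500L, 3500L, 900L),
    bin_id = c("5B", "5B", "5B", "2A"),
    stringsAsFactors = FALSE)

  # ---- QTL table: preset 19 QML + 5 YAL on BIN 5B ---------------------
  qtl <- rbind(
    data.frame(trait = .preset_qml_traits, qtl_type = "QML",
               bin_id = "5B", direction = "+", magnitude = NA_real_,
               significant = TRUE, stringsAsFactors = FALSE),
    data.frame(trait = .preset_yal_traits, qtl_type = "YAL",
               bin_id = "5B", direction = "-", magnitude = NA_real_,
               significant = TRUE, stringsAsFactors = FALSE),
    data.frame(trait = c("anthocyanin content", "fruit diameter"),
               qtl_type = c("QML", "YAL"), bin_id = "2A",
               direction = "+", magnitude = NA_real_, significant = FALSE,
               stringsAsFactors = FALSE))

  # ---- unigene placements (BLAST tabular) ------------------------------
  mk_hit <- function(q, s, pident, cov_pct, evalue) {
    qlen <- tgt_len[[q]]
    alen <- as.integer(round(cov_pct / 100 * qlen))
    data.frame(qseqid = q, sseqid = s, pident = pident, length = alen,
               mismatch = as.integer(round(alen * (100 - pident) / 100)),
               gapopen = 0L, qstart = 1L, qend = alen, sstart = 1001L,
               send = 1000L + alen, evalue = evalue, bitscore = 2 * alen,
               stringsAsFactors = FALSE)
  }
  placements <- rbind(
    mk_hit(uni_ids[1], bac_ids[1], 90.0, 95.0, 1e-180),  # boundary accept
    mk_hit(uni_ids[2], bac_ids[1], 97.6, 96.25, 1e-200),
    mk_hit(uni_ids[3], bac_ids[1], 89.9, 99.0, 1e-150),  # boundary reject
    mk_hit(uni_ids[5], bac_ids[2], 95.0, 97.0, 1e-170),
    mk_hit(uni_ids[6], bac_ids[3], 98.0, 98.0, 1e-190))  # BAC unanchored

  # ---- expression ------------------------------------------------------
  expression <- do.call(rbind, lapply(uni_ids, function(u) {
    base <- stats::runif(1, 4, 10)
    vals <- round(base + cumsum(stats::rnorm(length(.expr_stages), 0,
                                             0.8)), 2)
    data.frame(unigene_id = u, stage = .expr_stages,
               stage_index = seq_along(.expr_stages), value = vals,
               stringsAsFactors = FALSE)
  }))

  # ---- precursor megablast hits (for gene-negative BAC sites) ----------
  prec_src <- list(
    list(idx = 3, prec = "sim-MIR395a", evalue = 1e-60),
    list(idx = 4, prec = "sim-MIR395b", evalue = 1e-52),
    list(idx = 5, prec = "sim-MIR395c", evalue = 1e-40))
  precursor_hits <- do.call(rbind, lapply(prec_src, function(h) {
    p <- planted[[h$idx]]
    data.frame(target_id = p$spec$target_id, start = p$start, end = p$end,
               precursor_id = h$prec, evalue = h$evalue,
               stringsAsFactors = FALSE)
  }))

  # ---- ground-truth manifest ------------------------------------------
  feat_overlap <- function(tid, s, e) {
    f <- gene_features[gene_features$seq_id == tid &
                         gene_features$start <= e &
                         gene_features$end >= s, , drop = FALSE]
    sort(unique(f$source))
  }
  bins_of <- function(tid) {
    if (tid %in% markers$seq_id) {
      sort(unique(markers$bin_id[markers$seq_id == tid]))
    } else {
      hits <- placements[placements$qseqid == tid &
                           placements$pident >= 90 - 1e-9, , drop = FALSE]
      hits$coverage <- hits$length / tgt_len[hits$qseqid] * 100
      hits <- hits[hits$coverage >= 95 - 1e-9, , drop = FALSE]
      anchored <- hits$sseqid[hits$sseqid %in% markers$seq_id]
      sort(unique(markers$bin_id[markers$seq_id %in% anchored]))
    }
  }
  manifest <- do.call(rbind, lapply(planted, function(p) {
    ch <- feat_overlap(p$spec$target_id, p$start, p$end)
    bins <- bins_of(p$spec$target_id)
    data.frame(
      mirna_id = p$spec$mirna_id, target_id = p$spec$target_id,
      target_kind = tgt_kind[match(p$spec$target_id, tgt_ids)],
      strand = p$spec$strand, start = p$start, end = p$end,
      profile = .profile_string(p$spec$profile),
      expected_score = p$expected_score, curated = p$curated,
      gene_hit = length(ch) > 0,
      channels = paste(ch, collapse = ","),
      bins = paste(bins, collapse = ","),
      stringsAsFactors = FALSE)
  }))

  bundle <- list(mirnas = mirnas, targets = targets,
                 gene_features = gene_features, markers = markers,
                 qtl = qtl, expression = expression,
                 placements = placements,
                 precursor_hits = precursor_hits, manifest = manifest,
                 seed = seed, paths = NULL)

  if (!is.null(out_dir)) {
    bundle$paths <- write_bundle(bundle, out_dir)
  }
  bundle
}

#' Write a fixture bundle to disk
#'
#' Emits mirnas.fasta, bacs.fasta, unigenes.fasta, annotations.gff3 (gene
#' models + genetic_marker features), marker_map.tsv, placements.tsv
#' (12-column BLAST tabular), qtl.tsv, expression.tsv (wide),
#' precursor_hits.tsv and manifest.json.
#'
#' @param bundle list from [simulate_bundle()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  paths <- c(mirnas = pth("mirnas.fasta"), bacs = pth("bacs.fasta"),
             unigenes = pth("unigenes.fasta"),
             gff3 = pth("annotations.gff3"),
             marker_map = pth("marker_map.tsv"),
             placements = pth("placements.tsv"), qtl = pth("qtl.tsv"),
             expression = pth("expression.tsv"),
             precursor_hits = pth("precursor_hits.tsv"),
             manifest = pth("manifest.json"))
  write_fasta(bundle$mirnas$id, bundle$mirnas$sequence, paths[["mirnas"]])
  bac <- bundle$targets[bundle$targets$kind == "BAC", ]
  uni <- bundle$targets[bundle$targets$kind == "UNIGENE", ]
  write_fasta(bac$id, bac$sequence, paths[["bacs"]])
  write_fasta(uni$id, uni$sequence, paths[["unigenes"]])
  gf <- bundle$gene_features
  gene_lines <- sprintf(
    "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=gene%03d;Note=%s",
    gf$seq_id, gf$source, gf$start, gf$end, gf$strand,
    seq_len(nrow(gf)), gf$hit_definition)
  mk <- bundle$markers
  marker_lines <- sprintf(
    "%s\tSGN_marker\tgenetic_marker\t%d\t%d\t.\t+\t.\tID=mk%03d;Name=%s;map=%s;bin=%s",
    mk$seq_id, mk$position, mk$position, seq_len(nrow(mk)), mk$name,
    mk$map_name, mk$bin_id)
  writeLines(c("##gff-version 3", gene_lines, marker_lines),
             paths[["gff3"]])
  utils::write.table(
    data.frame(name = mk$name, map = mk$map_name, bac = mk$seq_id,
               position = mk$position, bin = mk$bin_id),
    paths[["marker_map"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$placements, paths[["placements"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  q <- bundle$qtl
  utils::write.table(
    data.frame(trait = q$trait, qtl_type = q$qtl_type, bin = q$bin_id,
               direction = q$direction, magnitude = q$magnitude,
               significant = q$significant),
    paths[["qtl"]], sep = "\t", quote = FALSE, row.names = FALSE)
  ex <- bundle$expression
  wide <- stats::reshape(ex[, c("unigene_id", "stage", "value")],
                         idvar = "unigene_id", timevar = "stage",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$unigene_id), ]
  utils::write.table(wide, paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$precursor_hits, paths[["precursor_hits"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = bundle$seed,
         mirnas = bundle$mirnas[, c("id", "species", "length")],
         planted = bundle$manifest,
         qtl_counts = as.list(table(paste(bundle$qtl$bin_id,
                                          bundle$qtl$qtl_type)))),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
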