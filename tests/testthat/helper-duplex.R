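# Test helpers: independent duplex construction and reference scorers.
# The brute-force scorers here re-derive classification, penalties and
# window sums from first principles so they stay independent of the
# package's scoring path.

.h_wc <- c(A = "T", C = "G", G = "C", U = "A")      # miRNA -> target (DNA)
.h_wob <- c(G = "T", U = "G")

# Build a duplex_alignment directly from a miRNA sequence and an edit
# profile (pos, edit), bypassing the scanner. Coordinates are nominal.
make_duplex <- function(mirna_seq, profile = NULL, mirna_id = "mirX",
                        target_id = "tgtX") {
  m <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  L <- length(m)
  if (is.null(profile)) {
    profile <- data.frame(pos = integer(), edit = character())
  }
  mb <- character(0); tb <- character(0); mp <- integer(0)
  for (i in seq_len(L)) {
    ed <- profile$edit[profile$pos == i]
    if ("deletion" %in% ed) {
      mb <- c(mb, m[i]); tb <- c(tb, "-"); mp <- c(mp, i)
    } else if ("wobble" %in% ed) {
      stopifnot(m[i] %in% names(.h_wob))
      mb <- c(mb, m[i]); tb <- c(tb, .h_wob[[m[i]]]); mp <- c(mp, i)
    } else if ("mismatch" %in% ed) {
      bad <- setdiff(c("A", "C", "G", "T"),
                     c(.h_wc[[m[i]]], .h_wob[m[i]]))
      mb <- c(mb, m[i]); tb <- c(tb, bad[1]); mp <- c(mp, i)
    } else {
      mb <- c(mb, m[i]); tb <- c(tb, .h_wc[[m[i]]]); mp <- c(mp, i)
    }
    if ("insertion" %in% ed && i < L) {
      mb <- c(mb, "-"); tb <- c(tb, "A"); mp <- c(mp, NA_integer_)
    }
  }
  duplex_alignment(mirna_id, target_id, 1L, sum(tb != "-"), "+",
                   mb, tb, mp, L)
}

# Independent reference: classify one column from the base pair table
ref_classify <- function(m, t) {
  m <- chartr("T", "U", toupper(m)); t <- chartr("T", "U", toupper(t))
  if (m == "-" || t == "-") return("INDEL")
  pairs <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
  if (any(vapply(pairs, function(p) p[1] == m && p[2] == t, TRUE)))
    return("MATCH")
  if ((m == "G" && t == "U") || (m == "U" && t == "G")) return("WOBBLE")
  "MISMATCH"
}

# Independent reference: window-minimum score by explicit enumeration
ref_score <- function(aln, window_len = 20L) {
  cols <- aln$columns
  n <- nrow(cols)
  cls <- vapply(seq_len(n), function(k) {
    ref_classify(cols$mirna[k], cols$target[k])
  }, character(1))
  pos <- cols$mirna_pos
  L <- max(pos, na.rm = TRUE)
  # flanking consumed positions for each insertion column
  prev <- integer(n); nxt <- integer(n)
  last <- 0L
  for (k in seq_len(n)) {
    prev[k] <- last
    if (!is.na(pos[k])) last <- pos[k]
  }
  nx <- L + 1L
  for (k in rev(seq_len(n))) {
    nxt[k] <- nx
    if (!is.na(pos[k])) nx <- pos[k]
  }
  best <- Inf
  for (w in seq_len(L - window_len + 1L)) {
    hi <- w + window_len - 1L
    tot <- 0
    for (k in seq_len(n)) {
      inside <- if (is.na(pos[k])) {
        prev[k] >= w && nxt[k] <= hi
      } else {
        pos[k] >= w && pos[k] <= hi
      }
      if (!inside) next
      tot <- tot + switch(cls[k],
        MATCH = 0,
        WOBBLE = 0.5,
        INDEL = 2.0,
        MISMATCH = if (!is.na(pos[k]) && pos[k] >= 2 && pos[k] <= 7)
          1.5 else 1.0)
    }
    best <- min(best, tot)
  }
  best
}

# random RNA / DNA strings
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# random edit profile over the full plan space (used for scoring property
# tests; may be arbitrarily bad)
rand_profile <- function(mirna_seq, max_edits = 4L) {
  m <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  L <- length(m)
  k <- sample(0:max_edits, 1)
  if (k == 0) return(data.frame(pos = integer(), edit = character()))
  pos <- sort(sample(seq_len(L - 1L), k))
  edit <- vapply(pos, function(p) {
    opts <- c("mismatch", "insertion", "deletion")
    if (m[p] %in% c("G", "U")) opts <- c(opts, "wobble")
    sample(opts, 1)
  }, character(1))
  data.frame(pos = pos, edit = edit, stringsAsFactors = FALSE)
}

# deterministic mini-bundle shared by store/pipeline tests (fast: tiny
# sequences, generator verification on)
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_bundle(1, out_dir = file.path(tempdir(),
                                                       "binmir_bundle1"))
    }
    cache
  }
})

shared_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- shared_bundle()
      p <- b$paths
      cfg <- run_config(
        mirnas_fasta = p[["mirnas"]], bacs_fasta = p[["bacs"]],
        unigenes_fasta = p[["unigenes"]], gff3 = p[["gff3"]],
        marker_map = p[["marker_map"]], placements = p[["placements"]],
        qtl = p[["qtl"]], expression = p[["expression"]],
        precursor_hits = p[["precursor_hits"]],
        out_dir = file.path(tempdir(), "binmir_run1"))
      cache <<- run_pipeline(cfg)
    }
    cache
  }
})
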