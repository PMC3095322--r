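#' @useDynLib binmiR, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------- alphabets

.rna_alphabet <- c("A", "C", "G", "U")
.dna_alphabet <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, strips whitespace and converts T to U. Idempotent.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over A/C/G/U.
#' @export
normalize_rna <- function(x) {
  x <- gsub("[[:space:]]", "", toupper(x))
  chartr("T", "U", x)
}

#' Normalize a nucleotide string to the DNA alphabet
#' @param x character vector.
#' @return character vector over A/C/G/T (U converted to T).
#' @export
normalize_dna <- function(x) {
  x <- gsub("[[:space:]]", "", toupper(x))
  chartr("U", "T", x)
}

.check_alphabet <- function(seqs, ids, alphabet, what) {
  pat <- sprintf("^[%s]*$", paste(alphabet, collapse = ""))
  bad <- !grepl(pat, seqs)
  if (any(bad)) {
    stop(sprintf("non-nucleotide characters in %s record(s): %s",
                 what, paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

.reverse_chars <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings.
#' @return reverse complements.
#' @export
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Position-wise complement of a DNA string (no reversal)
#' @param x character vector of DNA strings.
#' @return complements.
#' @export
complement_dna <- function(x) {
  as.character(Biostrings::complement(Biostrings::DNAStringSet(x)))
}

# ------------------------------------------------------------------- FASTA

.read_fasta_raw <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(set) == 0 && length(readLines(path, warn = FALSE)) > 0 &&
      !any(startsWith(readLines(path, warn = FALSE), ">"))) {
    stop(sprintf("malformed FASTA in %s: no '>' header at line 1", path),
         call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  list(id = ids, seq = as.character(set))
}

#' Read mature miRNA sequences from FASTA
#'
#' Sequences are normalized to the RNA alphabet (T treated as U, internal
#' whitespace stripped). The species tag is taken as the id prefix before
#' the first hyphen (e.g. "sly-miR395a" -> "sly").
#'
#' @param path FASTA file; one record per mature miRNA.
#' @param min_len minimum accepted length (default 19).
#' @return data.frame with columns id, species, sequence, length.
#' @export
read_mirna_fasta <- function(path, min_len = 19L) {
  raw <- .read_fasta_raw(path)
  if (anyDuplicated(raw$id)) {
    stop(sprintf("duplicate miRNA id(s): %s",
                 paste(unique(raw$id[duplicated(raw$id)]), collapse = ", ")),
         call. = FALSE)
  }
  seqs <- normalize_rna(raw$seq)
  .check_alphabet(seqs, raw$id, .rna_alphabet, "miRNA")
  len <- nchar(seqs)
  if (any(len < min_len)) {
    stop(sprintf("miRNA record(s) shorter than %d nt: %s", min_len,
                 paste(raw$id[len < min_len], collapse = ", ")),
         call. = FALSE)
  }
  species <- ifelse(grepl("-", raw$id, fixed = TRUE),
                    sub("-.*$", "", raw$id), NA_character_)
  data.frame(id = raw$id, species = species, sequence = seqs,
             length = len, stringsAsFactors = FALSE)
}

#' Read target sequences (BACs or unigenes) from FASTA
#'
#' Sequences shorter than `min_len` (the scoring window) are skipped with a
#' warning rather than failing the whole file.
#'
#' @param path FASTA file.
#' @param kind "BAC" (genomic clone; both strands are scanned) or
#'   "UNIGENE" (transcript; sense strand only).
#' @param min_len minimum usable target length (default 20).
#' @return data.frame with columns id, kind, sequence, length.
#' @export
read_target_fasta <- function(path, kind = c("BAC", "UNIGENE"),
                              min_len = 20L) {
  kind <- match.arg(kind)
  raw <- .read_fasta_raw(path)
  if (anyDuplicated(raw$id)) {
    stop(sprintf("duplicate target id(s): %s",
                 paste(unique(raw$id[duplicated(raw$id)]), collapse = ", ")),
         call. = FALSE)
  }
  seqs <- normalize_dna(raw$seq)
  .check_alphabet(seqs, raw$id, c(.dna_alphabet, "N"), "target")
  len <- nchar(seqs)
  short <- len < min_len
  if (any(short)) {
    warning(sprintf("skipping %d target(s) shorter than %d nt: %s",
                    sum(short), min_len,
                    paste(raw$id[short], collapse = ", ")), call. = FALSE)
  }
  data.frame(id = raw$id[!short], kind = kind, sequence = seqs[!short],
             length = len[!short], stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#' @param ids,seqs parallel character vectors.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, width = 70L) {
  stopifnot(length(ids) == length(seqs))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# -------------------------------------------------------------------- GFF3

#' The six gene-prediction annotation channels
#'
#' Gene models come from four Augustus runs (tomato EST, potato EST, tomato
#' unigene and de novo hints), GenomeThreader spliced alignments, and BLASTX
#' against Arabidopsis peptides.
#'
#' @return character vector of channel names.
#' @export
annotation_channels <- function() {
  c("AUGUSTUS_TOMATO_EST", "AUGUSTUS_POTATO_EST", "AUGUSTUS_UNIGENE",
    "AUGUSTUS_DENOVO", "GENOMETHREADER", "BLASTX_ARATH")
}

#' Read gene models and genetic markers from GFF3
#'
#' Features whose source matches one of the six annotation channels (case
#' insensitive) become gene features; features of type `genetic_marker`, or
#' whose source matches `marker_source_regex`, become marker records.
#' Records with end < start are rejected individually and counted; unknown
#' sources are counted and skipped.
#'
#' @param path GFF3 file (1-based inclusive coordinates, as written).
#' @param marker_types GFF3 feature types treated as markers.
#' @param marker_source_regex regex on the source column marking markers.
#' @return list with elements `genes` (data.frame: seq_id, source, start,
#'   end, strand, hit_definition), `markers` (data.frame: name, map_name,
#'   seq_id, position, bin_id) and `skipped` (named counts).
#' @export
read_gff3_features <- function(path, marker_types = "genetic_marker",
                               marker_source_regex = "marker") {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  empty <- list(
    genes = data.frame(seq_id = character(), source = character(),
                       start = integer(), end = integer(),
                       strand = character(), hit_definition = character(),
                       stringsAsFactors = FALSE),
    markers = data.frame(name = character(), map_name = character(),
                         seq_id = character(), position = integer(),
                         bin_id = character(), stringsAsFactors = FALSE),
    skipped = c(bad_coords = 0L, unknown_source = 0L))
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0) return(empty)
  # pre-filter records with end < start: GRanges would refuse the whole file
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok_cols <- lengths(fields) >= 8
  st <- suppressWarnings(as.integer(vapply(fields, function(f)
    if (length(f) >= 5) f[4] else NA_character_, character(1))))
  en <- suppressWarnings(as.integer(vapply(fields, function(f)
    if (length(f) >= 5) f[5] else NA_character_, character(1))))
  bad <- !ok_cols | is.na(st) | is.na(en) | en < st
  n_bad <- sum(bad)
  if (n_bad > 0) {
    message(sprintf("read_gff3_features: rejected %d record(s) with end < start or malformed columns", n_bad))
  }
  keep <- body[!bad]
  if (length(keep) == 0) {
    empty$skipped["bad_coords"] <- n_bad
    return(empty)
  }
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c("##gff-version 3", keep), tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")
  src <- as.character(gr$source)
  type <- as.character(gr$type)
  meta <- S4Vectors::mcols(gr)
  get_attr <- function(nm) {
    if (!nm %in% colnames(meta)) return(rep(NA_character_, length(gr)))
    v <- meta[[nm]]
    if (methods::is(v, "List") || is.list(v)) {
      vapply(as.list(v), function(x) {
        if (length(x) == 0) NA_character_ else
          paste(as.character(x), collapse = ",")
      }, character(1))
    } else {
      as.character(v)
    }
  }
  is_marker <- type %in% marker_types |
    grepl(marker_source_regex, src, ignore.case = TRUE)
  chan <- match(toupper(src), annotation_channels())
  is_gene <- !is_marker & !is.na(chan)
  n_unknown <- sum(!is_marker & is.na(chan))
  if (n_unknown > 0) {
    message(sprintf("read_gff3_features: skipped %d record(s) with unrecognized source", n_unknown))
  }
  nm <- get_attr("Name")
  id <- get_attr("ID")
  note <- get_attr("Note")
  genes <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr))[is_gene],
    source = annotation_channels()[chan[is_gene]],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    hit_definition = ifelse(is.na(note[is_gene]), "", note[is_gene]),
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  markers <- data.frame(
    name = ifelse(is.na(nm[is_marker]), id[is_marker], nm[is_marker]),
    map_name = toupper(get_attr("map")[is_marker]),
    seq_id = as.character(GenomicRanges::seqnames(gr))[is_marker],
    position = GenomicRanges::start(gr)[is_marker],
    bin_id = get_attr("bin")[is_marker],
    stringsAsFactors = FALSE)
  list(genes = genes, markers = markers,
       skipped = c(bad_coords = n_bad, unknown_source = n_unknown))
}

# ---------------------------------------------------------- BLAST tabular

#' Read 12-column BLAST tabular output
#'
#' Standard `-outfmt 6` columns. When `query_lengths` is supplied (a named
#' integer vector, typically from the companion FASTA), per-hit query
#' coverage is computed as alignment length / query length x 100.
#'
#' @param path tab-separated file, 12 columns, no header.
#' @param query_lengths optional named vector of query lengths (nt).
#' @return data.frame with the 12 standard columns plus `coverage`
#'   (NA when the query length is unknown).
#' @export
read_blast_tab <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- cols
    out$coverage <- numeric(0)
    return(out)
  }
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 12)) {
    stop(sprintf("BLAST tabular parse error in %s: expected 12 columns, got %d at line %d",
                 path, nf[which(nf != 12)[1]], which(nf != 12)[1]),
         call. = FALSE)
  }
  out <- utils::read.delim(text = lines, header = FALSE, col.names = cols,
                           stringsAsFactors = FALSE)
  out$pident <- as.numeric(out$pident)
  out$evalue <- as.numeric(out$evalue)
  out$coverage <- NA_real_
  if (!is.null(query_lengths)) {
    ql <- query_lengths[out$qseqid]
    out$coverage <- as.numeric(out$length) / as.numeric(ql) * 100
  }
  out
}

# ------------------------------------------------------------- TSV tables

#' Read the marker-to-BIN map table
#'
#' Expected tab-separated columns: `name`, `map`, `bac`, `position`, `bin`.
#' Map names must be EXPEN1992 or EXPEN2000; BIN labels follow the
#' chromosome-number + letter pattern (e.g. "5B").
#'
#' @param path TSV file with header.
#' @return data.frame with columns name, map_name, seq_id, position, bin_id.
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "map", "bac", "position", "bin")
  if (!all(need %in% names(tab))) {
    stop(sprintf("marker map %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(name = as.character(tab$name),
                    map_name = toupper(as.character(tab$map)),
                    seq_id = as.character(tab$bac),
                    position = as.integer(tab$position),
                    bin_id = as.character(tab$bin),
                    stringsAsFactors = FALSE)
  bad_map <- !out$map_name %in% c("EXPEN1992", "EXPEN2000")
  if (any(bad_map)) {
    stop(sprintf("unknown genetic map name(s): %s",
                 paste(unique(out$map_name[bad_map]), collapse = ", ")),
         call. = FALSE)
  }
  bad_bin <- !grepl("^[0-9]+[A-Z]+$", out$bin_id)
  if (any(bad_bin)) {
    stop(sprintf("malformed BIN label(s): %s",
                 paste(unique(out$bin_id[bad_bin]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(out[, c("name", "map_name")])) {
    stop("duplicate (marker, map) pairs in marker map", call. = FALSE)
  }
  out
}

#' Read the QTL trait table (QML and YAL records)
#'
#' Expected columns: `trait`, `qtl_type` (QML or YAL), `bin`; optional
#' `direction`, `magnitude` and `significant`.
#'
#' @param path TSV/CSV file with header (separator sniffed from extension).
#' @return data.frame with columns trait, qtl_type, bin_id, direction,
#'   magnitude, significant.
#' @export
read_qtl_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("trait", "qtl_type", "bin")
  if (!all(need %in% names(tab))) {
    stop(sprintf("QTL table %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  qt <- toupper(as.character(tab$qtl_type))
  if (!all(qt %in% c("QML", "YAL"))) {
    stop("qtl_type must be QML or YAL", call. = FALSE)
  }
  if (any(!nzchar(as.character(tab$bin)))) {
    stop("QTL records must carry a non-empty BIN", call. = FALSE)
  }
  data.frame(trait = as.character(tab$trait), qtl_type = qt,
             bin_id = as.character(tab$bin),
             direction = if ("direction" %in% names(tab))
               as.character(tab$direction) else NA_character_,
             magnitude = if ("magnitude" %in% names(tab))
               as.numeric(tab$magnitude) else NA_real_,
             significant = if ("significant" %in% names(tab))
               as.logical(tab$significant) else NA,
             stringsAsFactors = FALSE)
}

#' Read an expression matrix keyed by unigene id
#'
#' Wide tab-separated input (first column `unigene_id`, remaining columns
#' one per developmental stage, in order) returned in long format.
#'
#' @param path TSV file with header.
#' @return data.frame with columns unigene_id, stage, stage_index, value.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "unigene_id" || ncol(tab) < 3) {
    stop("expression table must have a unigene_id column plus >= 2 stages",
         call. = FALSE)
  }
  stages <- names(tab)[-1]
  long <- data.frame(
    unigene_id = rep(tab$unigene_id, each = length(stages)),
    stage = rep(stages, times = nrow(tab)),
    stage_index = rep(seq_along(stages), times = nrow(tab)),
    value = as.numeric(t(as.matrix(tab[, -1, drop = FALSE]))),
    stringsAsFactors = FALSE)
  long
}
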