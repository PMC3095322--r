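---
title: "Scoring, scanning and co-location methods in binmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, scanning and co-location methods in binmiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binmiR)
```

`binmiR` predicts plant miRNA target sites on transcript (unigene) and
genomic (BAC) sequences, curates them with a positional mismatch penalty
score, annotates them against predicted genes, places their carriers on
the genetic BINs of the *S. pennellii* introgression-line map, and joins
everything with fruit QTL and expression data in an SQLite store. This
vignette explains the model behind each stage, the tunable parameters and
their defaults, the numerical conventions, and what the bundled synthetic
data does and does not establish.

## The curation score

The scientific core is a penalty score over an antisense duplex between a
mature miRNA (5'→3') and a target subsequence. Each alignment column is
classified as a Watson–Crick pair, a G:U wobble, a mismatch, or an indel
(T and U are equivalent throughout). Penalties, keyed to the miRNA
position counted from the 5' end:

* wobble — 0.5 at any position (a wobble is *not* a mismatch);
* indel — 2.0 per gapped column, at any position;
* mismatch — 1.5 at positions 2–7, 1.0 elsewhere.

Positions 2–7 form the seed region, where pairing is most critical for
target recognition, hence the heavier mismatch charge. Scores are always
computed over 20 nt: an L-nt miRNA has L − 19 windows of 20 consecutive
miRNA positions; each window sums the penalties of the columns consuming
its positions plus any insertion columns lying between its first and last
position, and the site score is the minimum over windows. A site is
retained when its score is strictly below 3 — a score of exactly 3.0 is
rejected.

```{r score-demo}
m <- "UGGAGUGUGUCAGUCACGAAG"                      # 21-nt miRNA
cols <- strsplit(m, "")[[1]]
partners <- c(A = "T", C = "G", G = "C", U = "A")[cols]
partners[10] <- "G"                               # U10 becomes a G:U wobble
aln <- duplex_alignment("demo-miR", "demo-target", 1, 21, "+",
                        cols, unname(partners), seq_len(21), 21)
score_duplex(aln)
```

Three readings of this rule set were genuinely open and are resolved as
follows:

* *Seed zone extent.* "Any position different of 2 or 7" is read as
  "outside the range 2–7", consistent with the companion clause assigning
  1.5 to "position 2-7" and with the seed-region literature. Positions 1
  and 8+ therefore carry 1.0. The literal reading "≠ 2 and ≠ 7" would
  contradict the 1.5 clause and is not adopted.
* *Absolute vs window-relative seed.* The seed test uses the absolute
  miRNA position ("from the 5' end of the miRNA"), not the
  window-relative one. `scoring_params(window_relative_seed = TRUE)`
  exposes the alternative for sensitivity analysis only.
* *Gap length.* Each gapped column costs 2.0 independently, so a 2-nt
  bulge costs 4.0; per-column charging keeps the score additive over
  columns, which run-level charging would not.

Scores are sums of multiples of 0.5, but the retention comparison still
uses a 1e-9 tolerance so float arithmetic can never flip a boundary case.

## The scanner

Upstream of scoring, candidate duplexes must be found. Pipelines of this
kind often delegate the step to an external scanner such as miRanda;
`binmiR` implements its own banded antisense local alignment so the
stage is self-contained without an external binary, and treats the downstream penalty score —
not the scanner — as the arbiter of what survives. Scanner defaults
(`scan_params()`): Watson–Crick +5, G:U wobble +2, mismatch −3, gap open
−8, gap extend −2, at most 3 indel columns per duplex, and at least 90%
of miRNA positions paired (Watson–Crick or wobble) for a candidate to be
reported. These are declared defaults of this implementation, not a claim
of identity with any particular external scanner version.

Search works in "scan space": a strand-derived string in which the bases
pairing miRNA positions 1, 2, … appear left to right. For every anchor
the banded dynamic program finds the maximum-score alignment of the full
miRNA; ties are resolved to the lexicographically smallest operation
string under pair < deletion < insertion, realised by greedy forward
reconstruction over exact suffix optima (alignment scores are integers,
so ties are exact). The band limits the *total* number of indel columns
to 3, which also bounds the column count by miRNA length + 3.
`scan_exhaustive()` re-derives the same candidates by depth-first
enumeration of every gap placement (with a ≤10 kb target guard) and must
agree element-wise with the banded search — a property the test suite
checks across 100 seeded fixtures.

Policy choices fixed by this implementation: unigenes are scanned
on the sense strand only (they are mRNAs; a site on the antisense strand
of a transcript is not a target site), BACs on both strands with
coordinates always reported in the plus-strand frame; overlapping
candidates of one miRNA whose starts chain within 3 nt are merged keeping
the lowest penalty score. Penalty ties are broken by the higher scanner
alignment score before the leftmost-start rule — a perfect duplex can
otherwise be displaced by a variant of the same locus padded with
terminal defects that the 20-nt window excludes — then by leftmost start
and shortest span, making results fully deterministic. miRNAs shorter
than the 20-nt window (19-nt entries are legal input) cannot be
window-scored and are skipped with a warning.

## Annotation, BIN placement, precursor curation

A curated site is called "yes" when its interval shares ≥1 base
(1-based inclusive coordinates, strand-agnostic — a site on either strand
of a gene locus is reportable) with a predicted gene from any of six
channels: Augustus against tomato EST, potato EST, tomato unigene and de
novo hints, GenomeThreader, and BLASTX against Arabidopsis peptides. All
six flags are stored; the aggregate is the OR over a configurable channel
set defaulting to all six, so the narrower "any Augustus modality"
reading remains queryable. Hit definitions concatenate overlapping
feature annotations, deduplicated, ordered by start then source, so
exports are diff-stable.

BACs take the union of the BINs of their anchored markers over both
genetic maps (EXPEN1992, EXPEN2000); when the maps disagree the union is
kept and both evidence items exposed rather than arbitrating between
maps.
Unigenes inherit the BINs of every anchored BAC they align to at ≥90%
identity *and* ≥95% coverage, boundaries inclusive; coverage is alignment
length / *query* (unigene) length × 100, the standard reading for placing
a transcript on a genome. Site-level BINs are always inherited from the
carrier sequence, never computed independently. For curated sites that
hit no gene, alignments against known precursor sequences are curated at
e-value ≤ 1e-50 (inclusive); passing sites are flagged putative precursor
loci. The package consumes standard 12-column BLAST tabular files for
both placements and precursor hits rather than running the aligner
itself; megablast settings used to produce such files (e.g. -G 3 -E 2
-W 20 with the low-complexity filter) are recorded as provenance, not
re-implemented.

## The store and query surface

`build_store()` writes 16 tables, enumerated in `store_schema()`; the
relational layout is this package's own design. Only curated sites are
persisted; foreign keys
are validated before writing and the build aborts listing offenders.
Expression profiles are stored long-format (unigene, stage, value) so the
stage set is not baked into the schema. Row orderings are fixed and no
timestamps enter data tables, so rebuilding from identical inputs
reproduces every table except provenance. Queries go by BIN, miRNA,
target, or case-insensitive keyword over hit definitions and QTL trait
text, return the four display fields (co-located QTL, target BIN, hit
definition, rendered alignment) plus the expression profile when the
target has one, and export to RFC-4180-style CSV or a static HTML table,
both byte-stable. The alignment rendering convention — miRNA on top
5'→3', target below 3'→5', `|` for Watson–Crick, `:` for wobble — is
a convention declared by this package.

## Synthetic data: what it emulates and what it does not

`simulate_bundle(seed)` generates the complete input set at toy scale:
miRNAs (20–24 nt), BACs (3–6 kb) and unigenes (800 nt) with planted
target sites realized from explicit edit profiles, gene features covering
all six channels, markers, a marker→BIN map, QTL and expression tables,
BLAST-tabular placements (including exact-boundary rows at 90.0%/95.0%
and 89.9%), precursor hits straddling the 1e-50 cutoff, and a JSON
manifest of ground truth. The "miR395-like" preset mirrors the
proof-of-concept narrative used in the documentation: three clustered
precursor-style loci on one BAC between two markers (CT53/TG432 names)
flanking a BIN labelled 5B, unigene targets annotated as ATP-sulfurylase
homologs, and 19 QML + 5 YAL rows for that BIN. All identifiers carry a
`SIM`/`sim` tag; no real database identifiers are reproduced.

Two design rules make the ground truth sound:

* *Expected scores are computed independently.*
  `profile_expected_score()` works directly on the edit profile (penalty
  arithmetic over windows), never on an alignment, so the generator's
  truth and the pipeline's `score_duplex()` are two separate routes to
  the same number; the tests require them to agree.
* *Background complementarity is suppressed.* After planting, every
  target is scanned over all loci and strands; backgrounds producing any
  spurious sub-threshold site — or letting a planted site be rescued into
  a better-scoring variant (e.g. a pairing base adjacent to a planted
  deletion) — are resampled. Random edit profiles are restricted to at
  most two non-pairing edits, keeping every sub-threshold plant above the
  scanner's 90% pairing gate, and indels are kept away from window
  boundaries so a gap cannot drift across them into a different score.

Consequences for interpretation: passing end-to-end tests show the
pipeline recovers exactly what was planted under these controlled
conditions — correct coordinates, scores, gene flags, BIN inheritance and
QTL joins. They do not show robustness to features of real data that the
generator deliberately omits: repetitive and low-complexity genomic
sequence (where near-threshold spurious sites are common), heterogeneous
real-world GFF3 dialects, fragmented or chimeric unigene assemblies, or
scanner sensitivity beyond the declared coverage gate. Problem sizes used
by the default suite — targets of a few kb, ~10 planted sites, 100
scan-oracle fixtures and 1000 random duplexes for the property tests —
were chosen as the smallest sets that exercise every code path and
boundary; the generator scales to larger bundles through its size
arguments.

## Degenerate inputs and numerical conventions

Coordinates are 1-based inclusive everywhere a user sees them (GFF3
convention); interval arithmetic converts at the boundary. Targets
shorter than 20 nt are skipped with a warning; GFF3 records with end <
start are rejected individually and counted; unknown annotation sources
are counted and skipped, since real genome-browser GFF3 files are
heterogeneous (the marker-feature whitelist — type `genetic_marker` or a
source matching "marker" — is configurable for the same reason). Empty
files yield empty tables, not errors. Threshold comparisons (score
strictly < 3, identity/coverage ≥, e-value ≤) use the stated boundary
senses, with 1e-9 relative tolerances guarding float arithmetic. All
randomness in the generator derives from the single mandatory seed;
scanning, scoring, mapping and store construction are fully
deterministic.
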