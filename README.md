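# binmiR

Plant miRNA target-site discovery, penalty-score curation, and
genetic-BIN/QTL co-location for tomato introgression-line genetics.

## The problem

Mature plant miRNAs (~20–24 nt) guide cleavage of mRNAs carrying
near-perfect antisense target sites. In tomato, fruit metabolic QTL (QML)
and yield-associated loci (YAL) have been mapped at the resolution of the
*Solanum pennellii* introgression-line BINs — defined chromosome segments
anchored by the markers of the TOMATO-EXPEN1992 and -EXPEN2000 genetic
maps. Asking *"which predicted miRNA–target interactions co-locate with
which fruit QTL?"* requires chaining several otherwise standard steps:
scanning miRNAs against transcript (unigene) and genomic (BAC) sequences,
curating the candidate duplexes, annotating them against predicted genes,
placing their carrier sequences onto BINs, and joining the result with QTL
and expression tables. `binmiR` implements that chain as a reusable R
toolkit with an embedded SQLite store as its final product.

## The curation score

A candidate duplex is written as aligned columns along the miRNA
(5'→3'). Each column is classified and charged a positional penalty:

| column                              | penalty |
|-------------------------------------|---------|
| Watson–Crick pair                   | 0       |
| G:U wobble (not counted a mismatch) | 0.5     |
| insertion / deletion (per column)   | 2.0     |
| mismatch at miRNA positions 2–7 (seed) | 1.5  |
| mismatch elsewhere                  | 1.0     |

Scores are always computed over 20 nt: for an L-nt miRNA every run of 20
consecutive miRNA positions is summed (insertion columns are charged to
the windows that span them) and the **minimum** window sum is the site
score. Sites are retained only when the score is **strictly below 3**.

Candidate duplexes are produced by the package's own banded antisense
local alignment (Watson–Crick +5, wobble +2, mismatch −3, gap open −8 /
extend −2, at most 3 indel columns, ≥90% of miRNA positions paired). BACs
are scanned on both strands, unigenes on the sense strand only.
Overlapping candidates within 3 nt are merged keeping the lowest penalty
score. An exhaustive enumeration scanner (`scan_exhaustive()`) serves as
a test oracle for the banded search.

Downstream, curated sites are called "yes"/"no" by ≥1 nt overlap with
predicted genes from six annotation channels (Augustus × {tomato EST,
potato EST, unigene, de novo}, GenomeThreader, BLASTX vs Arabidopsis
peptides); BACs inherit BINs from their anchored markers (union over both
maps); unigenes inherit the BINs of BACs they align to at ≥90% identity
and ≥95% query coverage (inclusive); gene-negative sites with a precursor
hit at e-value ≤ 1e-50 are flagged as putative precursor loci.

## Worked example

Everything runs offline from a seeded synthetic bundle; the "miR395-like"
preset plants three clustered precursor-style loci on a BAC between two
markers flanking BIN 5B, plus unigene targets, 19 QML + 5 YAL rows for
that BIN, and negative controls scoring 3.0 and 3.5.

```r
library(binmiR)
b <- simulate_bundle(1, out_dir = tempfile("bundle"))
p <- b$paths
cfg <- run_config(mirnas_fasta = p[["mirnas"]], bacs_fasta = p[["bacs"]],
                  unigenes_fasta = p[["unigenes"]], gff3 = p[["gff3"]],
                  marker_map = p[["marker_map"]],
                  placements = p[["placements"]], qtl = p[["qtl"]],
                  expression = p[["expression"]],
                  precursor_hits = p[["precursor_hits"]],
                  out_dir = tempfile("run"))
res <- run_pipeline(cfg)
res$report
#>           candidates              curated        annotated_yes
#>                   15                    8                    5
#>         annotated_no precursor_candidates     mapped_sequences
#>                    3                    2                    5
#>         mapped_sites        colocated_qtl
#>                    7                   26
```

15 candidate duplexes were found, 8 survive the score < 3 filter (the two
planted negatives at 3.0 and 3.5 do not), 5 overlap a predicted gene, 2
gene-negative BAC sites carry a precursor hit below 1e-50, and 7 curated
sites inherit a BIN from their carrier. One curated duplex, a single G:U
wobble (score 0.5):

```r
scan(list(id = "sly-simR395a", sequence = b$mirnas$sequence[1]),
     list(id = "SIM-U3001", kind = "UNIGENE",
          sequence = b$targets$sequence[b$targets$id == "SIM-U3001"]))[[1]]
#> <duplex> sly-simR395a x SIM-U3001 [301-321] (+)
#> miR 5' UGGAGUGUGUCAGUCACGAAG 3'
#>        |||||||||:|||||||||||
#> tgt 3' ACCTCACACGGTCAGTGCTTC 5'
```

Querying the store by keyword joins sites with the QTL of their BIN:

```r
rows <- query_store(res$store, by = "keyword", term = "fructose")
unique(rows[, c("site_id", "mirna_id", "target_id", "bin_id",
                "qtl_trait", "score")])
#>    site_id     mirna_id target_id bin_id        qtl_trait score
#> 1 site0008 sly-simR395a SIM-U3001     5B fructose content   0.5
#> 2 site0009 sly-simR395a SIM-U3002     5B fructose content   1.5
#> 3 site0011 sly-simR395a SIMBAC001     5B fructose content   0.0
#> 4 site0012 sly-simR395a SIMBAC001     5B fructose content   1.0
#> 5 site0013 sly-simR395a SIMBAC001     5B fructose content   2.5
export_rows(rows, "fructose.csv", "csv")   # or "html"
```

A thin shell front end (`inst/cli/binmir.R`) exposes the stages as
subcommands (`simulate`, `scan`, `score`, `annotate`, `map-bins`, `run`,
`query`).

## The store

`build_store()` writes a single SQLite file with 16 tables (species,
mirnas, sequences, bacs, unigenes, sites, alignments, annotations,
gene_features, markers, bins, bin_assignments, qtl, expression,
precursor_hits, provenance). The schema is this package's own design for
the 16-table layout such databases use.
Only curated sites are persisted; all foreign keys are validated before
writing, and rebuilds from identical inputs are identical outside the
provenance table.

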