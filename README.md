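# mexscan

Micro-exon discovery and domain-level evolutionary analysis for plant
transcription-factor families.

## The problem

Micro-exons — exons whose coding length is at most 51 nt — are strikingly
concentrated inside two protein domains of plant transcription factors: the
AP2 DNA-binding domain of the *AP2/ERF* family and the K-box coiled-coil
domain of MIKC-type *MADS*-box genes. Studying them requires a chain of
small but error-prone steps: calling short coding exons from a GFF3
annotation, projecting their genomic coordinates through spliced,
phase-shifted CDS models into protein space, intersecting them with
Pfam-style domain hits, classifying genes by domain architecture, and
comparing the evolutionary constraint of the micro-exon windows against the
domains that contain them. `mexscan` implements that chain end to end for
anyone analysing plant (or other) genome annotations, with a synthetic-data
generator that plants ground truth for every stage.

## What it computes

* **Micro-exon calling** — one record per exon of the representative
  (longest-protein) isoform whose CDS-overlapping portion is 1–51 nt
  (threshold configurable), with genomic, CDS-offset and protein-residue
  coordinates (partial codons flagged).
* **Family classification** from domain architecture: ≥2 AP2 domains → *AP2*
  subfamily; AP2+B3 → *RAV*; AP2+other → "other"; a lone AP2 → *ERF/DREB*;
  SRF-TF (MADS-box) + K-box → *MIKC*.
* **Micro-exon typing**: the recurrent AP2-domain classes R1M1/R1M2/R1M3
  (9/26/31 nt in the first AP2 repeat) and R2M1 (45 nt in the second), and
  the tandem K-box pair M1/M2.
* **Ka/Ks** (Nei–Gojobori 1986 counting, equal pathway weighting,
  Jukes–Cantor correction) on codon alignments and arbitrary sub-windows,

      Ks = -3/4 ln(1 - 4/3 · Sd/S),   Ka = -3/4 ln(1 - 4/3 · Nd/N),

  with a one-sided Wilcoxon signed-rank comparison (exact null for n ≤ 25)
  of micro-exon windows against whole domains.
* **Neighbor-joining trees** of domain sequence sets (Poisson-corrected
  distances, Saitou–Nei Q-criterion, column-resampling bootstrap supports),
  written as newick.

## Worked example

```r
library(mexscan)

# a fully specified synthetic cohort with planted micro-exon architectures
cfg <- synthetic_config(seed = 42)
generate_genome(cfg, "sim")

res <- run_scan("sim/genome.fa", "sim/annotation.gff3", "sim/domains.tsv",
                out_dir = "sim/out")
res$summary
#>     group domain n_microexons n_in_domain  fraction
#> 1 AP2/ERF    AP2          125          96 0.7680000
#> 2    MIKC  K-box           52          48 0.9230769
#> 3     all    any          177         144 0.8135593
table(res$families$subfamily)
#>      AP2 ERF/DREB    other      RAV
#>       24      113        2        4
```

The summary reads: of the 125 micro-exons found in *AP2/ERF*-family genes,
96 (76.8%) fall inside an AP2 domain; of the 52 micro-exons in *MIKC*
genes, 48 (92.3%) fall inside the K-box — exactly the proportions this
cohort was built to carry, because the generator plants in-domain counts
deterministically. `sim/out/` holds the per-gene family table, the
per-micro-exon table (coordinates, domain, type, tandem group), the overlap
summary and a JSON run manifest.

A thin command-line wrapper with `simulate` and `scan` subcommands lives at
`inst/scripts/mexscan.R`.

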