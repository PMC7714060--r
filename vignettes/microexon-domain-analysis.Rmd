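---
title: "Micro-exons in AP2 and K-box domains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-exons in AP2 and K-box domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mexscan)
```

## Overview

`mexscan` analyses the placement and evolutionary constraint of micro-exons
— coding exons of at most 51 nt — relative to the AP2 domain of *AP2/ERF*
transcription factors and the K-box domain of MIKC-type *MADS*-box genes.
This vignette documents the models and procedures, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## Coordinate model

Every coordinate inside the package is **0-based, half-open** `[start,
end)`; interval length is always `end - start`. GFF3 and InterProScan files
use 1-based fully-closed coordinates, and the conversion happens exactly
once, at the I/O boundary (`coord_from_1based()` / `coord_to_1based()`).
A single internal convention keeps the projection code free of off-by-one
adjustments, which is where pipelines of this kind usually go wrong.

A transcript's CDS is modelled as an ordered set of genomic segments in
transcript (5'→3') orientation — descending genomic start on the minus
strand — with the GFF3 `phase` of the first segment trimmed before
translation (missing phases are treated as 0, the Ensembl convention being
that phase is always present). `build_coordinate_map()` pairs genomic
intervals with contiguous CDS offsets; projections between protein residues
and genomic blocks are pure arithmetic on those blocks. A genomic interval
that cuts a codon maps to the *covering* residue interval with
partial-codon flags: overlap questions need a superset of touched residues,
never a subset.

## Micro-exon calling and typing

An exon is a micro-exon when its **CDS-overlapping portion** is 1–51 nt.
The UTR part of a terminal exon does not count: UTR bases cannot overlap a
protein domain, which is the quantity of interest downstream. (Whether the
51-nt rule should apply to the full exon length instead is a genuinely open
reading; the threshold and the CDS-portion rule are both explicit,
configurable choices.) First and last coding exons are eligible — the K-box
M2 micro-exon sits at the domain's C terminus and would vanish under a
terminal-exon exclusion.

Domain assignment intersects the micro-exon's (closed) residue interval
with the protein's domain hits; a single residue of overlap suffices by
default (`min_overlap_aa = 1`, the most permissive reading of "overlaps"),
the largest overlap wins, and ties go to the N-terminal-most hit so the
result is deterministic. AP2 hits carry repeat labels R1, R2, … numbered
from the N terminus.

Micro-exon types are table-driven (`default_type_config()`): R1M1/R1M2/R1M3
are 9/26/31 nt in the first AP2 repeat, R2M1 is 45 nt in the second; the
coding length must match exactly (tolerance 0 nt). Tandems are maximal runs
of micro-exons at consecutive exon indices; members of a K-box tandem are
labelled M1, M2, … from 5' to 3'.

Enrichment summaries use the family as denominator: the AP2 fraction is
computed over all micro-exons of *AP2/ERF*-family genes, the K-box fraction
over all micro-exons of *MIKC* genes; a genome-wide row (any domain) is
reported alongside, since the two denominators answer different questions.
Empty groups report a missing fraction rather than 0.

## Family classification

Classification uses only the representative isoform — the transcript with
the longest protein, ties broken by the lexicographically smallest
transcript id so reruns are identical. Rules, in priority order: ≥2 AP2
domains → *AP2* subfamily (repeat duplication defines the subfamily, so
three repeats still qualify); 1 AP2 + ≥1 B3 → *RAV* (B3 beats "other"
because it is the more specific architecture); 1 AP2 + any other labelled
domain → "other"; a lone AP2 → *ERF/DREB*; otherwise, SRF-TF + K-box →
*MIKC* (SRF-TF alone, the type-I MADS architecture, is excluded). The
accession→label map is configuration; by default both PF00847 and PF00876
map to AP2 so tables written against either Pfam vocabulary are accepted,
and unmapped accessions are retained as label `"other"` rather than
dropped. Overlapping same-label hits on one protein are merged into their
union before repeat numbering, since domain scanners often report split
envelopes for one region.

## Ka/Ks

The implemented estimator is **NG86** (Nei–Gojobori counting): per-codon
synonymous site fractions with stop-creating single-nucleotide changes
excluded from numerator and denominator; pairwise differences averaged over
all minimal mutational pathways (1, 2 or 6 orderings), pathways through
stop codons excluded; Jukes–Cantor correction
`K = -3/4 ln(1 - 4/3 p)`, undefined when `p ≥ 3/4`; the ratio is missing
when `Ks = 0`. Codon columns with gaps, ambiguous bases or stops are
skipped entirely (complete-codon deletion). NG86 was chosen over
transition/transversion- and codon-frequency-aware estimators because it is
fully specifiable and testable against exhaustive enumeration at desk
scale, and the claims the pipeline supports are ordinal (micro-exon window
versus whole domain); a Yang–Nielsen-style estimator would slot in behind
the same `kaks()` surface.

`kaks()` accepts a region — an alignment-column interval or a union of
intervals — so micro-exon windows and whole domains are measured on the
same codon alignment; restricting to a union of disjoint windows sums site
and difference counts exactly.

Paired window-vs-domain comparisons use a one-sided Wilcoxon signed-rank
test. For n ≤ 25 the p-value comes from the exact null distribution,
computed by a generating-function convolution over (doubled) midranks —
exact even under ties; above that, the normal approximation with continuity
and tie corrections. Pairs with a missing ratio and zero differences are
dropped and counted.

## Alignment, distances, trees

Pairwise protein alignment is global Needleman–Wunsch with affine gaps
(a length-k gap costs `gap_open + k·gap_extend`; defaults 10 and 1,
BLOSUM62 scoring), with a fixed traceback preference — diagonal, then up,
then left — so optimal-tie alignments are reproducible. Codon back-threading
replaces residues by their codons and gaps by `---`.

Multiple-sequence alignment is deliberately out of scope: domain sets are
aligned pairwise to a reference (the longest member, ties by name) and
mapped onto its columns, dropping insertions relative to the reference
(`align_to_reference()`). For the closely related, nearly equal-length
domain sequences this pipeline trees, that profile is adequate and keeps
the alignment stage verifiable against brute force; it is *not* a general
MSA and degrades when sequences differ radically in length.

Distances are Poisson-corrected (`-ln(1 - p)` on the mismatch fraction over
both-ungapped columns); a saturated pair (`p = 1`) is flagged and set to a
cap (default 10) rather than infinity so neighbor joining stays finite.
Neighbor joining is the standard Saitou–Nei Q-criterion agglomeration with
two determinism rules: negative branch lengths are clamped to 0, and Q-ties
are resolved by the smallest (i, j) index pair. Bootstrap supports resample
alignment columns with replacement, rebuild distances and the NJ tree per
replicate, and report bipartition frequencies (0–100) on the full-data
tree; the replicate count and seed are explicit.

## The synthetic-data generator

`generate_genome()` is first-class, tested code, not a fixture. It emits a
genome FASTA, a GFF3 annotation, an InterProScan-style domain table and a
JSON ground truth, built codon-consistently from per-subfamily blueprints:

* *AP2*-subfamily genes (260 aa) carry two AP2 domains at residues
  [30, 98) and [150, 218) and the four planted micro-exons: R1M1 (9 nt),
  the tandem R1M2+R1M3 (26+31 nt) and R2M1 (45 nt), all inside their
  domains. The 26/31-nt exons split codons, so non-zero CDS phases are
  exercised by construction.
* *MIKC* genes (220 aa) carry SRF-TF at [2, 59) and K-box at [75, 165),
  with the tandem pair M1 (42 nt) + M2 (45 nt) ending exactly at the K-box
  C terminus. Individual K-box micro-exon lengths are less stereotyped in
  real annotations than the combined region they encode (a ~29-residue
  C-terminal motif covered by exactly two tandem micro-exons), so
  42+45 nt = 29 codons was fixed once as the default and not revisited.
* ERF/DREB, RAV, "other" and domain-less genes complete the cohort; RAV is
  single-exon, matching the architecture typical of that subfamily.

In-domain proportions are **planted deterministically**: the generator
computes the exact number of extra 9-nt linker micro-exons (outside any
domain, at most two per AP2 gene, one per MIKC gene) needed so that
in/(in+out) equals the requested fraction after rounding. The defaults —
24 AP2-subfamily genes (96 in-domain, 29 linker → exactly 76.8%) and 24
MIKC genes (48 in-domain, 4 linker → exactly 92.3%) — were chosen so that
the canonical enrichment fractions are exactly representable with whole
micro-exons; the surrounding cohort (113 ERF/DREB, 4 RAV, 2 other) mirrors
a rice-scale family census.

Within a family, genes descend from a common ancestral CDS and diverge by
the same substitution process as `evolve_pair()` (synonymous proposals
always accepted, nonsynonymous with probability ω, stop-creating rejected;
defaults ω = 0.2, per-gene Ks 0.15), so family members are genuinely
homologous and the alignment/Ka/Ks/tree stages see realistic input.
`evolve_pair()` measures realized synonymous divergence by NG86 counting on
the true pair during simulation — the stopping rule is decoupled from
whatever estimator is later pointed at the output. Intron and UTR lengths
are uniform on [60, 500] and [50, 200] nt; chromosome background is i.i.d.
A/C/G/T at 0.25 each; each gene sits on its own chromosome; strands are
Bernoulli(0.5) unless forced.

What the generator does **not** emulate: splice-site motifs, indels,
codon-usage bias, overlapping genes, pseudogenes, assembly gaps, or
annotation errors. Passing the planted-truth tests therefore demonstrates
the correctness of the pipeline's bookkeeping and estimators under clean
input, not robustness to the pathologies of real annotations.

## Numerical and degenerate-input choices

* Translation uses the standard genetic code only; one trailing stop is
  trimmed; ambiguous codons become `X`; internal stops flag the transcript
  invalid (excluded with a warning) rather than aborting the run.
* A CDS segment outside every exon, or a CDS length not a multiple of 3
  after phase trimming, likewise invalidates only that transcript.
* In the degenerate NG86 case where *every* pathway between two codons
  passes through a stop, all pathways are used with steps into/out of stops
  counted as nonsynonymous (the alternative — dropping the codon pair —
  would silently shrink Sd+Nd below the observed difference count).
* `evolve_pair()` errors when the target synonymous divergence is
  unreachable within a proposal cap (4000 proposals per codon).
* Zero-variance expression rows z-score to all-zero rather than NaN.

## Problem sizes

The test suite verifies NG86 against exhaustive pathway enumeration for all
61×61 sense-codon pairs, signed-rank exactness against full 2^n enumeration
for n ≤ 10, NJ against planted additive trees of 4–8 taxa, coordinate
projection round-trips over 1000 random transcripts on both strands, ω
recovery at 500 codons × 50 seeds for ω ∈ {0.1, 0.2, 0.5, 1.0} (mean
within ±0.05, ±0.1 at ω = 1), and the end-to-end planted-truth cohort at
its default size (177 genes); `scripts/acceptance.R` re-runs the cohorts
and a 20-seed ω recovery. These sizes are the package's chosen trade-off
between statistical resolution and a test suite that stays pleasant to run.

## Known limitations

* The star-profile alignment is not an MSA; trees of highly divergent or
  length-heterogeneous sequences should be built from a proper MSA
  upstream.
* NG86 ignores transition/transversion and codon-frequency bias; absolute
  Ka/Ks values on biased real data will differ from codon-model estimators
  even though orderings are typically preserved.
* Gene-pair selection for Ka/Ks is the caller's responsibility (an explicit
  pair list); the package does not infer orthology.
* JTT-style maximum-likelihood protein distances are not implemented;
  Poisson correction is the default and only distance.
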