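---
title: "Compact Cas12a library design and screen analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compact Cas12a library design and screen analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas12ascreen)
```

This vignette records the models this package implements, the
parameters that matter, and the design decisions taken where the design
was genuinely open. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## The design problem

Cas12a's intrinsic pre-crRNA processing lets one transcript encode
several spacers, each preceded by a ~20-nt direct repeat (DR). A compact
knockout library therefore assigns each gene four 23-nt spacers, split
either across two 2-spacer constructs (dual) or packed into one 4-spacer
construct (quad). The designer must pick spacers that (i) cut the
protein-coding function of the right isoform, (ii) avoid cutting other
genes, (iii) clone cleanly, and (iv) — because paired cuts excise the
intervening fragment — avoid deleting functional non-coding elements
that happen to sit between two spacers.

### Coordinates

Internal coordinates are **1-based closed** throughout, the IRanges
convention, because the whole R/Bioconductor interval stack is built on
it; GFF3 is already 1-based closed and BED (0-based half-open) is
converted by `rtracklayer` on import. This is purely an internal
convention — every gap and overlap rule below is defined in nucleotides
between or within physical intervals and is representation-independent.

### Candidate enumeration

A candidate is a TTTV PAM (either strand) followed by a 23-nt
protospacer. The predicted cut position is protospacer base 18 (0-based
from the PAM-proximal end), the approximate distal cut of Cas12a's
staggered break; a candidate belongs to a gene when this cut position
falls inside the canonical isoform's CDS. The canonical isoform is the
transcript whose annotation tag contains "canonical" (case-insensitive);
absent a tag, the longest-CDS transcript, ties broken by smallest
transcript id. The tag rule delegates to the annotation's own
designation; the fallback is this package's convention, since annotation
releases differ in how they flag genes that lack the tag.

### Hard filters

A spacer is discarded when any of the following holds:

| Filter | Rule | Why |
|---|---|---|
| POLY_T | ≥ 4 consecutive T | Pol III terminator truncates the transcript |
| GC_LOW / GC_HIGH | GC < 20% or > 80%, strict | duplex stability / specificity |
| RESTRICTION_SITE | GAATTC or GGTACC, either strand, in the DR+spacer cloning context | EcoRI/KpnI are used for cloning |
| AMBIGUOUS_BASE | any non-ACGT | not synthesisable as specified |

With 23-mers the GC bounds cannot be hit exactly (GC% is a multiple of
100/23), so strict-vs-inclusive is moot in practice: the attainable
range of retained spacers is [21.74%, 78.26%]. The restriction-site scan
runs again on the fully assembled oligo at cassette time, because a site
can span a junction that the candidate-level scan cannot see.

### Off-targets

`count_cds_offtargets()` counts genomic sites where an exact PAM is
adjacent to a ≤ 3-mismatch match of the spacer and the protospacer
window overlaps (≥ 1 nt) a CDS segment of *another* gene; the intended
site is excluded. Three mismatches is a configurable default, not a
sacred number — published off-target searches rarely state their budget.
"Overlaps" rather than "is contained in" was chosen because a cut one
base outside an exon boundary still disrupts the adjacent coding
sequence; the difference only matters within 22 nt of exon edges.

The search is seed-and-extend: a 23-mer with ≤ 3 mismatches must match
one of four disjoint pieces (widths 6, 6, 6, 5) exactly, so exact seed
lookups over an integer-coded genome followed by Hamming verification
find every site — the test suite proves equality against an exhaustive
sliding-window oracle. The same machinery, PAM-agnostic and genome-wide,
validates non-targeting controls.

### Ranking and selection

Filtered candidates are totally ordered: fewer CDS off-targets, then
Pfam-domain overlap, then cut site within the first 85% of the spliced
CDS, then higher on-target score, then genomic position (+ before −).
Pfam and the 85% rule are *priorities*, not filters: genes whose only
candidates sit in the last 15% of the CDS still get designs. Each
candidate's priority is its reverse rank, so selection maximises a sum
of integer priorities.

Dual selection picks 4 spacers as 2 pairs maximising summed priority
subject to: ≥ 25 nt end-to-start gap between the two protospacer
intervals of a pair (so the two nucleases do not compete for the same
footprint), ≥ 50 nt between the genomic spans of the two pairs, and no
pair span overlapping an annotated non-coding element (miRNA, tRNA,
lncRNA, rRNA, snRNA, snoRNA — the paired-cut deletion argument). Both
distances are **gaps between physical intervals**, not midpoint
distances, because both rules are about physical extents. Exon diversity
is a soft lexicographic bonus among equal-priority assignments
("when possible", not a constraint). The search is exhaustive over the
top-50 ranked candidates, implemented as branch-and-bound over feasible
pairs with a bound that cannot cut off the optimum; on ≤ 12-candidate
inputs the tests verify equality with full enumeration. Genes with no
feasible 4-spacer assignment fall back to one feasible pair
(`partial`) or `non_designable`.

Quad selection arranges 4 position-ordered spacers with the same 25-nt
adjacent-gap rule and span-level non-coding avoidance. A quad *targets*
an isoform when all four spacers cut within its CDS; the primary array
maximises the number of isoforms targeted (dynamic programme per
feasible chain), and when one array cannot cover every CDS-bearing
isoform, additional arrays are emitted for the remaining isoforms until
covered or infeasible. Candidates for quads are pooled across all
isoforms, since isoform-specific exons are invisible from the canonical
CDS alone.

### Controls and assembly

Non-targeting controls are random filter-clean 23-mers with **zero**
genomic matches at ≤ 3 mismatches on either strand, PAM-agnostic —
a stricter standard than targeting spacers face, appropriate for
controls meant to report no cutting at all. Cassettes are
`DR+spacer` repeated (single printed DR by default); multiplexed arrays
in real vectors use position-distinct DR variants, whose sequences are
vendor/vector-specific — the `drs` argument accepts any DR set, and the
default stand-in reuses the printed DR. Sense oligos prepend `TCCC`,
antisense oligos prepend `AAAC` to the reverse complement.

## The screen model

### Counting

Construct identity is established by the **position-1 spacer** after the
first DR anchor (exact 23-nt match; anchor location tolerates a
configurable 0–1 mismatches). Short single-end reads often do not cover
a whole 250–350 bp array, so position-1 identity is the default;
`verify_all = TRUE` additionally requires every array position to match,
for long reads. Position-1 spacers must be unique across the library
(checked, fatal), which the designer guarantees by construction. Every
read is assigned or counted unassigned; the identity
`assigned + unassigned = total` is asserted per sample in the tests.

At per-base error rate *e*, exact 23-nt matching bounds recall at
(1−e)²³ — at e = 0.01 that is ≈ 0.79, and no counter with this matching
rule can do better; the tests pin recall to this bound rather than to a
wishful number, and separately require ≥ 95% of assigned reads to agree
with the simulator's truth.

### Per-construct inference

Counts are normalised to log₂-CPM with pseudocount 0.5 (plain depth
normalisation; no trimmed-mean scaling, which the screen design does not
call for). Each construct gets a two-group least-squares fit. With
weights on, the mean–variance trend is estimated by lowess of
√(residual SD) on average log-CPM; per-observation SDs are predicted at
the fitted values and weights are the inverse predicted variances — the
voom idea, without sample-level quality weights (a documented
simplification; the array-weight estimation adds machinery that this
desk-scale reimplementation does not need to make its guarantees).

### Moderation

Residual variances are shrunk by empirical Bayes under a scaled
inverse-χ² prior. With `e_g = log s²_g − ψ(d_g/2) + log(d_g/2)`
(ψ the digamma function), the prior is estimated by method of moments:
`trigamma(d₀/2) = Var(e) − mean(trigamma(d_g/2))` (Newton inversion) and
`s₀² = exp(mean(e) + ψ(d₀/2) − log(d₀/2))`. When the observed spread is
no larger than chi-square sampling alone explains, d₀ = ∞ and every
posterior variance equals s₀²; when the variances are literally
identical, s₀² is their common value (the documented limit). The
moderated t uses d₀ + d_g degrees of freedom; F = t² for these
single-contrast designs. This is the classical non-robust estimator; the
robust refinement (outlier-variance down-weighting) is out of scope and
its absence means a few genuinely wild constructs can inflate d₀
slightly. The tests recover (d₀ = 4, s₀² = 0.25) from simulation and
agree with an independent reference implementation to < 5%.

### Gene aggregation

The gene statistic is the **mean moderated t** of the gene's constructs.
This is a deliberately simple, fully specified substitute for
rotation-based gene-set testing: it preserves the defining behaviour —
a gene whose constructs agree in direction scores more extreme than one
whose constructs oppose — in closed form. Directional two-sided
p-values come from N(0, 1/n) (default) or from an empirical null of
size-matched pseudo-genes resampled from non-targeting controls.
Because the moderated t has finite df, the normal null is slightly
anti-conservative: at total df ≈ 30 the gene-level type-I error at
α = 0.05 is ≈ 0.058, which the acceptance band [0.03, 0.07] absorbs;
with many NTCs the empirical null removes this approximation.
Benjamini–Hochberg q-values (hand-rolled step-up, tested against the
reference) complete the table; conventional hit thresholds are FDR 20%
for dual screens and 5% for quads, with logFC thresholds of 0
(enrichment), −5 (depletion) and 0.5 (growth advantage) for
over-representation analyses.

## The synthetic world

`simulate_genome()` does not draw genomes at random and hope: it
**plants** what the designer needs to be exercised. Every gene's CDS
carries canonical TTTV sites followed by filter-clean 23-mers at 80-nt
spacing (so within-pair and between-pair rules are satisfiable by
construction); 15% of genes get a 61-nt non-coding element between
candidate sites (so span rejection is exercised against planted truth);
25% of multi-exon genes get a second, exon-skipped isoform; half the
genes get a Pfam interval over the first half of exon 1. Background
sequence is uniform random and contributes additional, often
filter-failing candidates. Defaults (700–1200 nt CDS, 1–3 exons, 300-nt
intergenic gaps) give a ~0.7 Mb contig for 500 genes — small genes by
mammalian standards, but with realistic *local* structure, which is
what the design rules see.

`simulate_screen_counts()` draws negative-binomial counts
(`var = μ + φμ²`, φ = 0.05 — a typical pooled-screen overdispersion;
the paper-level parameters are 300× coverage and 6 replicates) around a
log-normal baseline abundance (sdlog 0.25) scaled per condition by
2^(planted logFC) and renormalised, so compositional shift — the
constant that pushes every measured logFC down when a few genes explode
— is reproduced. NTCs always carry logFC 0.

What a green test does **not** establish: performance on mammalian-scale
genomes (10³× larger search space), repeat- or pseudogene-rich
off-target landscapes (the synthetic background is uniform), PCR/chimera
artefacts in counting (not modelled), or the behaviour of the exact
gradient-boosted on-target scorer (the surrogate shares only the
interface and the PAM/GC/homopolymer direction of effect).

## Numerical notes

* GC percentages are exact multiples of 100/23; all bound checks are
  strict inequalities.
* Selection objectives are integers (priority sums × 10 + exon bonus
  ≤ 4), so optimality comparisons are exact and tie-breaks (genomic
  position, then + strand) are deterministic; identical inputs and seed
  give byte-identical library TSVs.
* The trigamma inversion uses Newton steps from `x = 0.5 + 1/y` (the
  standard starting point), converging in < 10 iterations over the
  relevant range; `y` outside [1e−6, 1e7] falls back to the asymptotes.
* Degenerate constructs (constant across samples) are excluded from
  moderation and assigned p = 1 rather than propagating zero variances.
* `bh_fdr` runs the step-up with a cumulative minimum from the largest
  p; permutation equivariance and agreement with the reference
  implementation are tested properties.

## Known limitations

* No GTF dialect, trans-splicing, or fuzzy coordinates on ingest.
* Off-target counting is CDS-restricted by design; no bulge/indel
  models.
* Two-group unpaired contrasts only; no multi-factor designs.
* The NTC empirical null resamples constructs independently and so does
  not model inter-construct correlation within a vector.
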