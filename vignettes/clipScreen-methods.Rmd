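---
title: "clipScreen: methods and modeling choices"
author: "clipScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clipScreen: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(clipScreen))
```

# Overview

clipScreen implements the computational route from raw iCLIP reads to
jointly paralog-controlled target exons: barcode handling and unique-cDNA
deduplication, single-nucleotide crosslink-site calling, significant-site
detection against a within-gene randomization null with 15-nt cluster
merging, pentamer enrichment and binding-site density, region-normalized
tag distributions, an exon enrichment screen, and percent-spliced-in (PSI)
knockdown-response classification with a paralog-compensation test. A
synthetic-data module generates inputs with the statistical structure the
analysis assumes, together with complete ground truth, so every stage can
be validated without external data.

This vignette explains the models behind each stage, the parameters that
matter, and the design choices made where the underlying procedures leave
room for interpretation.

# Crosslink sites and unique cDNAs

iCLIP reads truncate at the protein–RNA crosslink, so the nucleotide
immediately 5' (in transcript orientation) of a mapped read's start marks
the binding site. With 1-based in-memory coordinates this is `start - 1`
on the `+` strand and `end + 1` on the `-` strand; on disk all interval
files follow the BED 0-based half-open convention, for which the same rule
reads `s - 1` and `e` for a tag `[s, e)`. Sites that would fall off a
chromosome edge are discarded (and counted) rather than clamped.

A *unique cDNA* is one distinct combination of chromosome, strand,
strand-aware start position and random barcode. Only the truncation point
enters the key — two reads of different lengths from the same molecule are
duplicates. A consequence worth knowing: two genuinely distinct molecules
that collide on position *and* barcode are merged, exactly as in a real
experiment; with the default 5-nt random barcode this affects well under
1% of molecules at the simulated depths. Reads whose insert after barcode
removal is shorter than 11 nt are dropped (an insert of exactly 11 nt is
kept). Deduplication is performed per replicate, then replicates are
pooled for site calling; both behaviours are plain function calls, so the
alternative order is available to the user.

# The randomization null and site FDR

Significance of a crosslink site's height is assessed against a
within-gene randomization: each of `R` randomizations redistributes the
gene's observed unique-cDNA total uniformly (multinomially) over the
gene's positions, and the height census — the number of positions reaching
height at least `h` — is recorded. The FDR at height `h` is

$$\widehat{FDR}(h) = \min\left(1,\ \frac{\mathbb{E}_{null}\,\#\{pos:
height \ge h\}}{\#\{observed\ sites: height \ge h\}}\right),$$

made monotone non-increasing in `h`. The exact estimator used by the
original protocol this emulates is not restated in the source we follow;
the estimator above is our declared interpretation, and it is validated
against an exhaustive oracle: for a toy gene of span 10 with 3 cDNAs, all
$10^3$ equally likely placements can be enumerated, and the Monte-Carlo
estimate at `R = 5000` agrees within twice its Monte-Carlo standard error
(the closed form $L \cdot P(\mathrm{Binom}(n, 1/L) \ge h)$ gives the same
values by linearity of expectation). The default `R = 100` follows common
practice for this protocol; `alpha = 0.05` on the FDR defines significant
sites. Randomization is uniform over the full gene span; FDRs are computed
per gene with no cross-gene correction, matching the per-gene logic of the
protocol.

Significant sites within 15 nt of each other (boundary inclusive, measured
between crosslink positions) merge greedily into clusters. The cluster FDR
reported is the minimum member-site FDR; an optional second stage compares
cluster height sums with the maximal 15-nt window sums of the
randomizations (`method = "window"`), since the protocol wording supports
either reading.

# Pentamer enrichment and binding-site density

Pentamers (`k = 5`) are counted on the annotated strand in windows of
±30 nt around each crosslink site (the window choice is ours; the
procedure we follow does not state one, and both are exposed as
parameters). The null repeats the identical counting at positions
re-drawn uniformly within each site's gene span, `R = 100` times;
enrichment is the z-score against that null. K-mers with zero null
variance are reported with `z = 0` and flagged rather than infinite. The
top-10 set is taken by descending z with lexicographic tie-breaking.

Binding-site density of an exon is the percentage of its nucleotides
covered by at least one occurrence of any top k-mer (union coverage).
Density groups are compared with the two-sided independent two-sample
t-test with pooled variance — the era's default reading of "independent
two-sample t-test" — with Welch available behind a flag.

# Region assignment and size correction

Each unique cDNA is assigned by its single crosslink nucleotide to one of
six classes — 5'UTR, ORF, 3'UTR, intron, ncRNA, intergenic — with
precedence ncRNA > 3'UTR > 5'UTR > ORF > intron > intergenic where
annotations overlap (our choice; configurable). Raw percentages are counts
over the total; size-corrected percentages divide each class count by the
class's genomic footprint in nt and renormalize, which is what makes
exonic binding visible against the genomic dominance of introns and
intergenic space. Both vectors sum to 100 within 0.01.

# The exon screen

Candidate exons are scored by the number of unique cDNAs whose crosslink
position falls within the exon extended by 300 nt beyond either splice
site (boundary inclusive, clipped to the gene span), divided by the gene's
total unique-cDNA count. "Overall coverage within the same gene" is read
as the gene's total tag count, not a per-nucleotide rate; the ranking is
by score with deterministic tie-breaks (window count, then coordinate).
Windows of neighbouring exons may overlap; tags in the overlap count for
both.

# PSI, response classes and paralog compensation

PSI is `100 * included / (included + skipped)` on molar isoform
quantities. Knockdown contrasts use the pooled-variance two-sample t-test
on replicate PSI values, reported per exon without multiple-testing
correction by default (Benjamini–Hochberg behind a flag). Classification
uses the double-knockdown contrast: responsive above 15 PSI points
(exclusive), strongly responsive above 40, constitutive-like at control
PSI ≥ 95, fully constitutive at 100. The compensation score is
$S = |\Delta PSI_{double}| - \max(|\Delta PSI_\alpha|,
|\Delta PSI_\beta|)$; an exon is flagged paralog-compensated when
`S > 15` and both single-knockdown effects stay below 10 points (defaults,
configurable).

# The synthetic study

The generator emulates the statistical structure the analysis assumes,
not the sequencing process in detail.

**Genome and genes.** One random-sequence chromosome carries
non-overlapping genes (default 50): coding genes with five exons (first =
5'UTR, last = 3'UTR, middle = cassette exon, ~80–200 nt exons, 100–300 nt
introns), a 10% fraction of two-exon ncRNA genes. Forty percent of genes
receive a planted binding-site run in the centre of the cassette exon: a
concatenation of eight AGAA/GAA units in a random per-gene register
(24–32 nt), written strand-aware. The mixed register is deliberate — real
AGAA-rich binding regions vary in phasing, and it is this variation that
produces the junction pentamers (AGAAG, GAAAG, ...) a recovery analysis
should find alongside the core repeat pentamers.

**Reads.** Crosslinked molecules are drawn with per-position propensity
`expression × (b0 + w·motif)`, where `motif` indicates planted-run
positions (`b0 = 1`, `w = 50` by default; intergenic background at weight
0.01). Expression weights are log-normal (sdlog 0.5). Each read starts one
nucleotide downstream of its crosslink, with uniform 20–40 nt inserts; the
resulting crosslink share inside a planted run equals
`m(b0+w) / (m(b0+w) + (L-m)b0)` for run length `m` in a gene span of `L`
positions, recorded per gene in the ground truth. Each molecule gets a
random barcode; with probability 0.3 an emitted read is instead a PCR
duplicate of an earlier molecule, copying its position, length and
barcode. The default barcode layout `NNNXXXXNN` (5 random + 4 experiment
nt) is a common iCLIP arrangement. No sequencing errors are simulated, and
alignment is emulated by emitting the true intervals.

**Splicing.** Two paralogous factors have baseline activities
$E_\alpha = 0.15 \ll E_\beta = 1$. Knockdown leaves residual activity
`k = 0.05`. Cross-repression is rational de-repression:

$$e_\beta = k_\beta E_\beta \frac{1 + \gamma_r E_\alpha}
{1 + \gamma_r k_\alpha E_\alpha}, \qquad
e_\alpha = k_\alpha E_\alpha \frac{1 + \gamma E_\beta}
{1 + \gamma k_\beta E_\beta},$$

with $\gamma = 10 \gg \gamma_r = 1$: depleting the abundant factor
strongly de-represses the scarce one, and only weakly vice versa. True PSI
of exon $e$ is $100 \cdot \mathrm{logistic}(\theta_0 + d_e(e_\alpha +
e_\beta))$ with $\theta_0 = -1.5$ and dependence $d_e$ drawn from [2, 4]
for motif-carrying exons and 0 otherwise. The defaults were chosen from
the model algebra so that single knockdowns are almost exactly buffered:
after β-knockdown the de-repression gain of α is
$E_\alpha\gamma(1-k)E_\beta/(1+\gamma k E_\beta) = 0.95$, equal to the
lost β activity of $0.95$ — so the total activity, and with it PSI, barely
moves, while joint depletion collapses it. This functional form is a
modeling choice that encodes the qualitative biology (poison-exon
mediated asymmetric cross-repression), not a published formula. Replicate
PSI adds Gaussian noise (σ = 3 PSI points) clipped to [0, 100], and
measurements are emitted as included/skipped quantities of a 100-unit
molar total per sample.

**What passing tests do and do not show.** The simulation has flat
background propensity within genes, no mappability structure, no
sequencing errors, no expression changes upon knockdown and Gaussian PSI
noise. Recovery of planted signal therefore demonstrates correctness of
the statistical machinery under its own assumptions — not performance on
real libraries, where non-uniform background and mapping artefacts make
cluster and motif calls harder.

# Numerical and degenerate-input conventions

* All randomness is seeded; simulation, cluster and k-mer nulls use
  distinct derived streams, so reruns are byte-identical.
* FDRs are clamped to [0, 1] and monotonized over heights; zero-variance
  t-tests return `t = 0, p = 1` when means agree (and `p = 0` otherwise);
  zero-variance k-mers get `z = 0` plus a flag.
* Exons shorter than `k` get density 0 with a flag; empty site lists give
  all-zero k-mer counts; an empty tag set is an error for region
  assignment ("no tags").
* Ties are broken deterministically everywhere (lexicographic for k-mers;
  window count then coordinate for the screen).

# Problem sizes used in the validation suite

The bundled tests and the acceptance script run on desk-scale instances
chosen to exercise every code path with stable statistics: the reference
planted study uses 50 genes and 20,000 reads; null calibration uses 50
independent 6-gene simulations of 3,000 reads plus 1,000 dependence-free
exons for t-test calibration; the FDR oracle uses the exhaustively
enumerable span-10 gene. These sizes are the package's validation
conditions, and the corresponding quantities (recovery and spurious-call
rates, motif hit counts, AUC, type-I error) are computed fresh on every
run.

# Known limitations

* The randomization FDR estimator is an interpretation of a protocol that
  is cited rather than restated by the work this package follows.
* Region percentages depend on the annotation's class precedence; with
  real annotations containing overlapping transcripts the configurable
  precedence matters more than on the toy genome.
* The feedback model is phenomenological; it is not meant to estimate
  biochemical parameters, only to generate data with the joint-depletion
  signature at a controllable strength.
* PSI is taken from isoform quantities (capillary-electrophoresis style);
  estimating PSI from RNA-seq junction reads is out of scope.
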