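---
title: "Detecting failed Z dosage compensation from pooled embryo transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting failed Z dosage compensation from pooled embryo transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mascdose)
```

## The model

`mascdose` analyses the transcriptomic consequences of male killing in
WZ/ZZ insects, where infection suppresses the Z-linked masculinizer gene
(*Masc*) and with it male dosage compensation.  Everything rests on one
explicit dose model for a pooled, mixed-sex embryo RNA sample.

Let $m$ be the fraction of pool RNA from ZZ (male) individuals, and
$f \in [1, 2]$ the compensation-failure factor: the effective Z dose of one
male, where $f = 1$ means male Z output is repressed to the single-copy
female level and $f = 2$ means both copies are fully expressed.  Then the
pool-level expected dose is

$$
\text{dose}_g =
\begin{cases}
1 & g \text{ autosomal}\\
m\,f + (1 - m) & g \text{ Z-linked, infected pool}\\
1 & g \text{ Z-linked, uninfected (compensated) pool.}
\end{cases}
$$

The expected count of gene $g$ in a library is
$\mu_g = L \cdot b_g \,\text{dose}_g\, \pi_g / \sum_h b_h \pi^0_h$, where
$L$ is the library size, $b_g$ a lognormal baseline expression, $\pi_g$ the
Masc time profile (1 for every other gene) and $\pi^0$ its uninfected
version.  Counts are negative binomial with variance
$\mu + \phi\mu^2$ ($\phi = 0$ degenerates to Poisson).  Two consequences of
using the *baseline* composition as the denominator:

* an uninfected library totals $L$ in expectation, and per-gene
  infected/uninfected expectation ratios equal the dose model exactly
  (autosomes 1, Z genes $m f + 1 - m$);
* a compensation-failed library carries *excess* Z reads above $L$ —
  which is what extra transcription does.  Total-count conservation and
  exact per-gene dose ratios cannot both hold when the Z fraction of the
  transcriptome is non-negligible; we keep the dose ratios exact and let
  totals float, because every downstream statistic is ratio-based.

The Masc profile $\pi$ is piecewise linear through
$(0, 0.4), (6, 1), (12, 0.3), (18, 0.1)$ hpo, constant after 18: unimodal
with its maximum at 6 hpo and rapid decay, which is the qualitatively
established shape; the knot values are free parameters of the synthetic
world.  Infected pools use $d \cdot \pi$ with knockdown $d \in (0, 1]$.

## From counts to the Z-shift statistic

1. **CPM.** Each library is scaled to one million; all downstream
   statistics are ratios, so the within-sample scale is immaterial.
2. **M/A values.** $M = \log_2\frac{\bar x_I + c}{\bar x_U + c}$ and
   $A = \frac12 \log_2 (\bar x_I + c)(\bar x_U + c)$ with pseudocount
   $c = 0.5$ CPM (guards dropout contigs); contigs below 1 CPM in both
   groups are dropped as noise-dominated.
3. **Centering.** Per-sample normalization creates a compositional offset:
   if 20% of contigs are Z-linked and shift by $\times 1.5$, every CPM in
   that library is deflated by $\log_2 1.1 \approx 0.14$.  We subtract the
   median M of *autosomal* contigs — the invariant set of a Z-dosage
   analysis, the same assumption TMM/median-of-ratios normalization makes
   globally.  A global-median variant is available but is biased whenever
   the shifted class is a large transcriptome fraction (at a realistic
   28-chromosome karyotype the difference is negligible; at a synthetic
   5-chromosome one it is not).  Centering choice does not affect the test
   statistic below, which is a difference of medians.
4. **Summaries.** Per-chromosome median and quartiles (type-7 quantiles,
   stated so golden tests are bit-stable), Z first.
5. **Test.** Observed shift $= \text{median}(M_Z) - \text{median}(M_A)$;
   chromosome labels are permuted over contigs and the one-sided p-value is
   $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$.  With multiple
   timepoints, Benjamini–Hochberg across timepoints.

Under the dose model, $2^{\text{median}(M_Z)}$ (autosome-centred) recovers
$m f + 1 - m$; the test suite checks 5% recovery at $L \ge 10^6$,
$\ge 100$ Z genes, $\phi \le 0.1$, with three libraries per condition.
Note the permutation test is calibrated *on average over gene worlds*:
conditionally on one fixed gene set whose Z genes happen to be atypically
expressed, the size can deviate a little, so the null-calibration check
draws a fresh world per replicate.

## Homology assignment

Contigs are translated in all six frames (standard code; an internal stop
truncates a frame to its longest stop-free stretch) and searched against the
reference proteins with an affine-gap Smith–Waterman (Gotoh) implemented in
C++; a gap of length $k$ costs $11 + k$ under BLOSUM62, the de facto
protein-search default.  Significance is the Karlin–Altschul form
$E = K m n e^{-\lambda S}$ with the published ungapped BLOSUM62 constants
$\lambda = 0.3176$, $K = 0.134$ and $n$ the summed database length — a
reproducible closed form rather than an external search engine.  (Applying
ungapped constants to gapped scores makes the E-values conventional rather
than exact; all decisions use the standard $E < 10^{-9}$ cutoff, far from
the regime where the distinction matters.)  The best hit (score, then
E-value, then lexicographic gene id — determinism over elegance) sets the
chromosome; sub-threshold contigs are explicitly `unassigned`.  Global
(Needleman–Wunsch) alignment with the same scoring backs percent-identity
reporting, computed over columns where neither row is gapped (the
convention is stated because identity denominators vary across tools).
Both DP routines are verified against exhaustive alignment-enumeration
oracles.

## Molecular sexing

Dose ratio $= (1+E)^{\Delta Ct_{\text{sample}} - \Delta Ct_{\text{calibrator}}}$
with $\Delta Ct = Ct_{\text{ref}} - Ct_{\text{target}}$, efficiency
$E = 1$ by default (no standard curves to estimate it from), and the
calibrator taken from known-male controls (or 0 when baseline Cts
coincide, as in the simulator's default).  A WZ female has half the ZZ
template for Z-linked genes: dose ≈ 0.5 vs ≈ 1.  Calls require the two Z
genes to *agree*: both below 0.70 → female, both above 0.75 → male,
anything else ambiguous rather than silently misclassified.  The narrow
band is deliberate: with technical triplicates (the qPCR norm, and the
simulator default) the replicate-averaged $\Delta\Delta Ct$ noise at 0.15
cycles/well is ~0.12 cycles, so 0.70/0.75 leaves ≥ 3.4σ margins on both
sides.  A wider male threshold (e.g. 0.85, margin $\log_2(1/0.85) = 0.23$,
1.9σ) misroutes several percent of true males into the ambiguous band and
cannot reach 99% cohort accuracy at that noise level, which is why the
default high threshold sits at 0.75.  Brood sex ratios get an exact
two-sided binomial test (smaller tail doubled, capped at 1): 302 females
and 0 males gives $p = 2^{-301}$.

## Phylogenetics

The Masc family tree is built from the tandem zinc-finger block (residues
51–122, 1-based inclusive; all I/O coordinates are 1-based inclusive,
internal arrays 0-based half-open).  Distances are uncorrected p-distances
over columns where neither sequence is gapped (a Poisson correction
$-\log(1-p)$ is a flag; at domain-scale divergences the ranking rarely
changes).  Neighbor joining uses the standard Q criterion with two stated
determinism rules: Q ties join the smallest (row, column) pair, and
negative branch-length estimates are clamped to zero with the deficit moved
to the sister branch so the joined distance is preserved.  On additive
matrices the tree reproduces the input distances exactly (tested to 1e-9
against random tree metrics, with an exhaustive least-squares topology
oracle up to 6 taxa; beyond that, a zero-residual fit certifies the
topology because a tree metric determines its tree uniquely).  Bootstrap
resamples alignment columns with equal probability, rebuilds the NJ tree,
and reports per-split percentages, stored as node labels so they survive
newick round trips.

## Synthetic world: what a green test does and does not establish

The generator emulates: pooled RNA from 25–50 embryos of mixed sex
(`male_fraction` is an *input* per pool — male death is in progress during
infection and no mortality schedule is assumed); Z genes at copy 2 (ZZ)
vs 1 (WZ); compensation halving male Z output when intact; a failure
factor in infected pools (optionally ramped over development, mirroring
failure that becomes detectable only from mid-embryogenesis); Masc
knockdown peaking against a 6-hpo profile; NB count noise; and Ct values
for the two Z-linked sexing genes plus the autosomal normalizer.  Reference
proteins are uniform over the 20 canonical amino acids with synonymous
codons drawn uniformly, and contigs are CDSs with uniform point mutations.

Defaults: 28 chromosomes (the silkworm karyotype that anchors chromosome
assignment), 50 genes each, library $10^6$, $\phi = 0.05$, $m = 0.5$,
$f = 2$, $d = 0.2$, timepoints 0–48 hpo, 2% contig mutation rate, qPCR
base Ct 20 cycles (arbitrary; cancels in all dose ratios).

What it does *not* model: real codon usage, composition or repeat structure
(homology recovery on synthetic contigs is easier than on genuine
cross-species data, where 28% protein identity is typical for true
homologs); read-level artifacts, positional bias, assembly errors
(the pipeline starts from contigs and counts by design); biological
replicate variability beyond the NB dispersion; gene-length effects
(counts are per-contig, not length-normalized — ratios cancel length);
within-pool expression correlation.  A green acceptance suite therefore
establishes that the *statistical machinery* recovers known parameters
under the stated model, not that the biology of any particular dataset is
settled.

## Numerical and degenerate-input decisions

* Seeded operations restore the caller's RNG state; identical seeds are
  byte-identical.
* Quantiles: type 7 everywhere.
* Pseudocount 0.5 CPM; abundance filter 1 CPM in at least one group.
* All-zero libraries, empty groups, < 5 Z contigs, < 3 taxa, incomparable
  alignment pairs, sub-codon contigs and malformed newick all raise classed
  errors (or, for sub-codon contigs, a warning plus `unassigned`), named in
  the function documentation.
* p-distance pairs with zero comparable columns are an error naming the
  pair, not NA; triangle-inequality violations are permitted.
* Unknown amino acids score as `X` (neutral) rather than erroring, matching
  search-tool behaviour.
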