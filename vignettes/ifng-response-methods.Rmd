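---
title: "Methods: quantifying cell-type-resolved IFN-γ responses in sorted nuclei"
author: "ifngtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cell-type-resolved IFN-γ responses in sorted nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models behind each stage of the
package, the parameters that matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where the methods literature
leaves the details open.

# The experimental structure being modelled

The package targets experiments in which IFN-γ (or saline) is
delivered to brain tissue and the transcriptional response is read out
from sorted nuclei: bulk RNA-seq of NeuN+ (neuronal) versus NeuN−
(glial) gates across a 0/6/24/48/72 h time course, single-nucleus
RNA-seq across six major ventral-midbrain cell types, and
immunofluorescence of nuclear pSTAT1 as the signaling readout. The
quantities of scientific interest are (i) which genes respond, per
compartment and per cell type; (ii) the kinetic class of the response
(early-peaking at 6 h versus late-peaking at 24 h with slow decay);
(iii) the systematic 2–8-fold amplitude advantage of glia over
neurons; and (iv) strictly cell-type-restricted programs, MHC class II
in microglia above all.

# UMI demultiplexing and molecule collapse

Reads carry a cell barcode, a UMI and a gene tag. Barcode correction
is exact-match first; otherwise an observed barcode is corrected to a
whitelist member at Hamming distance 1 *only if that member is
unique* — with two candidates the read is rejected rather than
guessed, since "correcting all single-nucleotide errors" does not
license arbitration between equally close barcodes. Within each
(corrected barcode, gene) bucket, distinct UMIs form a graph with
edges at Hamming distance ≤ 1 and each connected component is one
molecule. Component collapse is the most literal reading of
"collapse UMIs within Hamming distance one"; the directional,
count-aware adjacency rule used by some UMI tools is intentionally not
applied. Two details the method description leaves open are decided
here and asserted in tests:

- **Representative UMI**: the component member with the highest read
  support, ties broken lexicographically. Any fixed rule works; this
  one is deterministic and order-independent.
- **Transitivity**: components are transitive closures, so a chain
  A–B–C with d(A,C) = 2 collapses to one molecule.

The implementation hashes each UMI's distance-1 neighbourhood
(36 strings for an 8-mer) into a union–find structure, giving
O(tags × length) behaviour per bucket; unit and acceptance tests
verify exact agreement with an exhaustive all-pairs oracle built on
igraph connected components.

# Marker specificity and type assignment

Expression is binarized at count > 0. For gene *g* in cluster *c*
(*k* expressing among *n* cells), the p-value is the one-sided
binomial tail `pbinom(k-1, n, p0, lower.tail = FALSE)` with `p0` the
out-of-cluster expressing fraction floored at 1/N (N = all cells);
the floor prevents a zero null for cluster-exclusive genes. The
specificity statistic is log₂ of the ratio of (floored) expressing
fractions. BH correction is applied within cluster. Markers are the
top 99 genes at log₂ specificity > 3 and FDR below 1e-49, ranked by
FDR then specificity. The FDR cutoff is read literally from the
convention "10e-50" = 1e-49; since 1e-50 may have been intended, the
threshold is an argument (`maxFdr`), and at the specificities involved
the choice is immaterial.

Cluster-to-type assignment takes, per cluster, the mean log₂
specificity of each candidate type's marker set and assigns the best
type if its mean is positive and leads the runner-up by a margin
(default 1 log₂ unit); otherwise the cluster is `UNASSIGNED`,
mirroring the practice of excluding ambiguous clusters that co-enrich
several types' markers. Upstream unsupervised clustering is an input,
not part of the package.

# Doublet filtering

The filter targets hybrid nuclei (e.g. a neuronal nucleus carrying an
oligodendrocyte profile). For each of three marker sets in order
(oligodendrocyte, astrocyte, microglia; the package takes any named
ordered list), and within each cell class other than the marker set's
own type, the per-cell sum of log₂(CPM+1) over the marker genes is
fitted with a two-component univariate Gaussian mixture by EM, and
cells scoring more than `kSd` (default 8) standard deviations above
the singlet component's mean are removed before the next round.
"Sum of expression" is ambiguous between counts and normalized
values; normalized is the default and a raw-count mode is exposed.

Numerical choices for the EM: initialization at the 25th/75th
percentiles with equal weights and half the pooled SD; convergence at
an absolute log-likelihood change below 1e-6 or 500 iterations;
components reported mean-ascending; a fit on fewer than 20 points or
on constant scores errors, and `filterDoublets` skips such a
class/round with a warning rather than removing cells.

Two robustness rules guard the thresholding, both motivated by a
failure mode observed during development: on a unimodal singlet score
distribution, the EM can park one component as a near-degenerate
spike on a narrow slice of the mode, and "8 SD above the first
component" then flags ordinary cells.

- The **singlet component is the dominant-weight component**, not
  blindly the lower-mean one: doublets are a small minority by
  construction, so a low-weight, low-mean component is an EM artefact.
- The two components only count as distinct modes when **Ashman's
  D = (m₂ − m₁)/√((s₁² + s₂²)/2) ≥ 2** (the standard
  distinguishability cutoff, `minSeparation`); below it the class is
  treated as a single singlet population and thresholded on its own
  mean + `kSd`·SD.

Fits are computed per class (not pooled across classes) because
different types have different baseline marker leakage; pooling makes
the singlet distribution multimodal and invites exactly the
pathology above. Fits are re-estimated each round on surviving cells,
matching the sequential description of the procedure.

# Single-nucleus differential expression

The procedure compares one cell type's cells between a treated and a
control sample in four steps, each seeded:

1. **Equalize cell numbers**: the larger group is subsampled without
   replacement to the smaller group's size.
2. **Equalize transcript depth**: the deeper group's counts are
   binomially thinned entrywise with p = (shallower mean
   total)/(deeper mean total). Postconditions — thinned ≤ original
   entrywise, realized mean within sampling error of the target — are
   asserted inside the function on every run (at 6 SE; tests verify
   tighter bounds).
3. **Rank-sum test** per gene on size-factor-normalized counts:
   median-of-ratios size factors where estimable, library-size
   factors otherwise (with sparse single-cell counts the
   geometric-mean reference usually vanishes). The rank test is
   invariant to monotone per-gene transforms, so only cross-cell
   scaling matters, which is why a simple size-factor substitute for
   pooling-based normalization preserves the test's meaning. The
   statistic is the Mann–Whitney U with tie correction and
   continuity-corrected normal approximation, matching
   `wilcox.test(correct = TRUE)` (verified gene-by-gene in tests);
   with both groups at ≤ 8 cells the exact enumeration is used.
   Genes with zero counts in both groups are excluded.
4. **BH correction and replicate intersection**: a gene is called up
   (down) only if it passes |log₂FC| > 3 (the > 8-fold rule) with
   consistent sign and FDR < 0.01 in *every* treated-vs-control
   comparison.

The log₂ fold change uses group means of normalized counts with a
pseudocount defaulting to the CPM-equivalent of 1 (1e-6 × mean
library size); the original procedure states no pseudocount, and this
choice only stabilizes genes near zero. One equalization draw is the
default; `nDraws > 1` averages p-values over draws as an extension.
An alternative threshold pair (|log₂FC| > 4, q < 0.05) appears in
some presentations of this analysis; both are reachable through the
`lfc`/`fdrThreshold` arguments, with the Methods-style pair as
default.

# Bulk time-course analysis

**Per-gene two-group test.** Tests are run on log₂(CPM+1) replicate
values. The default is limma's empirical-Bayes moderated t-test: at
4–6 replicates per group, per-gene variance estimates are unstable,
and the exact rank-sum alternative has a p-value floor of
2/C(10,5) ≈ 0.0079 at 5v5, which after BH correction across
thousands of genes can never reach FDR < 0.01 — the moderated test is
the field's standard answer at this design size. Plain Welch and the
exact rank-sum remain available via `method`. Fold changes are
computed on group-mean CPM with a 1-CPM pseudocount.

**DEG counts and the persistent core.** Per gate and timepoint, IFN
vs saline calls use |log₂FC| > 1 and FDR < 0.01; the overlap set
(same direction in both gates) is reported per timepoint. The
persistent core is genes called up in both gates at ≥ 3 timepoints;
with four timepoints, a strictly-greater reading of "> 3" would mean
all four, so "at least 3" is the default and both readings are
selectable (`strictlyGreater`).

**Kinetics.** `kineticsProfile` reports mean ± SEM (SD/√n) of
log₂(CPM+1) per gene, gate and timepoint, with all saline replicates
pooled at t = 0; single-replicate cells get `NA` SEM.

**Interaction test.** The gate-differential effect statistic is the
linear contrast (glia IFN − glia saline) − (neuron IFN − neuron
saline) of replicate group means. Its null distribution comes from a
Freedman–Lane permutation: the additive gate + treatment fit is held
fixed and its residuals are permuted within gates. Permuting raw
treatment labels is *not* a valid interaction null — for a gene with
a strong but equal effect in both gates, label permutations scramble
that main effect into spuriously large interaction statistics — and
the Freedman–Lane scheme is the standard fix. 1,000 permutations and
BH at FDR < 0.05 are the defaults; permutation indices are shared
across genes for speed, and tests verify null uniformity on a
hand-built no-effect design.

**Response modules.** Among interaction-significant genes, module
rules follow the qualitative definitions: `purple` = up-called in
both gates with a larger glial effect; `green` = neuron-high baseline
(log₂ difference > δ), glia-only up; `orange` = neuron-high baseline,
glia-only down; `yellow` = glia-high baseline, glial down; all else
`UNCLASSIFIED`. "Highly expressed in one compartment but not the
other" has no published magnitude, so δ defaults to 1 on the log₂
scale and is an argument.

# Normalization and signatures

log₂(CPM+1) is exact: CPM columns sum to 10⁶ before the log, and the
transform is invariant to scaling a cell's counts. Z-scores use the
population SD (divisor n); the difference from the sample SD is
immaterial at realistic n but must be pinned down for exact tests.
Signature scores are *sums* of normalized values over the signature's
genes (matching how MHC signature scores are usually displayed); an
averaging mode exists for comparing signatures of unequal size.
Bundled signatures: MHC-I = {H2-K1, H2-D1, B2m, Tap1}, MHC-II =
{H2-Ab1, H2-Eb1, H2-Aa, Cd74}; the same sets ship as plain-text
gene-set files under `inst/extdata/`.

# Image quantification

The 2-SD marker threshold needs an "image background" that no
published definition pins down numerically. The default estimator is
robust: background level = image median; background SD = root mean
square deviation of sub-median pixels from the median, which is a
consistent estimator of the noise SD for symmetric noise and is
insensitive to bright objects (a plain mean/SD mode is exposed). On
pure Gaussian noise the resulting mask's false-positive rate matches
the 2-SD tail P(Z > 2) ≈ 2.3%, which the tests verify. ROI classes
come only from the TH/NeuN marker masks (an ROI is marker-positive
when more than half its pixels fall in the mask), never from the
signal channel. Per-ROI quantification is the mean signal intensity
minus the whole-image median — shift-invariant and possibly negative.
Max projection of z-stacks is provided as a trivial preprocessing
step; segmentation itself is an input (label mask), as in the manual
workflow the package mirrors.

# The synthetic-data generator

Every generator is a pure function of a `SimConfig` and its seed, and
every output carries complete ground truth (per-read parent
molecules, per-cell types and doublet flags, per-gene program
classes, per-ROI classes and painted intensities).

**What it emulates.** Six cell types at the published composition
(1,241 oligodendrocytes, 194 astrocytes, 134 microglia, 437 dopamine,
1,257 GABAergic, 1,436 VGLUT2 nuclei); negative-binomial
(gamma-Poisson) counts per gene and type — the standard overdispersed
choice, with dispersion as a config knob since no generative model is
published; marker genes elevated `markerFold` (default 30×) in their
own type; ISGs whose IFN amplitude is `isgFoldNeuron` (default 4×) in
neurons and that times a per-gene Uniform(2, 8) factor in glia;
MHC-II genes near-silent at baseline everywhere (5% of a normal
gene's mean) and induced only in microglia; doublets as unscaled sums
of two independently drawn parents of different types (maximizing
marker co-enrichment, the signature the filter keys on), optionally
restricted to specific host/partner types; barcode/UMI substitution
errors at one substitution per tag per read at most (keeping the
Hamming-1 regime well-posed) and Poisson PCR duplicates; a bulk
design with 5 replicates per gate × treatment × timepoint and saline
at every timepoint; early kinetics peaking at 6 h and late kinetics
peaking at 24 h with slow decay (the late-decay shape leaves
fold^0.7 — about 8-fold at a typical glial amplitude — at 72 h, and
the 24 h peak is sized to be resolvable at replicate-level noise);
and disk-shaped nuclei of the three pSTAT1 classes painted on a noisy
background.

Two composition safeguards keep the bulk series realistic: marker
genes are capped at 30% of a gate's library mass, and the *extra*
mass contributed by induced genes at full induction is capped at 5%
(`inducedShare`). Without these caps, per-replicate CPM normalization
couples every gene to the induction program — at a 20% induced-mass
share, all other genes' CPM dips at the response peak, which distorts
planted kinetics in a way real transcriptomes (where ISGs are a small
mass fraction) do not show. Similarly, off-type marker expression
leaks at 8% of a gene's base mean, mirroring the few-percent off-type
detection rates of lineage markers in real nuclei data; this keeps
binomial specificity strong while making singlet marker-sum scores a
continuous distribution a Gaussian mixture can describe, rather than
a sparse count lattice.

**What it does not emulate.** Ambient RNA and batch effects;
read-level FASTQ or alignment artefacts; spatial structure in images
beyond non-overlapping disks; cluster-level substructure within the
six types (cluster labels equal type labels in the truth); and any
claim that the default depth or dispersion matches the original
study, which does not report them — both are config-exposed. Passing
tests on this generator therefore demonstrate correctness of the
*computations* under a faithful statistical structure, not robustness
to every artefact of real data.

# Problem sizes used in validation

The test suite and the acceptance script run deliberately compact
designs: 200 random read tables of up to 1,000 reads for the collapse
oracle; ~9,500 molecules at 1% tag error for demultiplexing recovery;
460-cell, 1,000-gene matrices (5 and 20 seeds) for the doublet
filter; 100 cells per group and 1,200 genes (10–20 seeds) for the DE
calibration and power checks; 2,000 points for mixture recovery; a
2,000-gene, 80-replicate series for the bulk analyses; and 256×256
images for the quantification operators. These sizes give stable
pass/fail behaviour for the statistical properties being checked
while keeping a full validation run in the minutes range.

# Known limitations

- The doublet filter can only see doublets whose second parent
  carries one of the supplied marker programs; neuron–neuron doublets
  are invisible to glial marker sets, by design.
- The binomial specificity test treats cells as exchangeable within
  and outside the cluster; batch or sample structure is not modelled.
- The permutation interaction test needs ≥ 3 replicates per
  gate × treatment cell, and its p-value floor is 1/(nPerm + 1).
- `rankSumDE`'s normal approximation is what the tie structure of
  UMI counts requires at realistic group sizes; at very small groups
  the exact path takes over, with its coarse p-value grid.
- TIFF I/O stores 16-bit integers; arbitrary-unit intensities are
  rounded on write.
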