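---
title: "Detecting the adeno-to-squamous tipping point with dynamic network biomarkers"
author: "astDNB authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the adeno-to-squamous tipping point with dynamic network biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astDNB)
```

## Background

Lung adenocarcinomas (ADC) carrying combined *KRAS* activation and *LKB1*
loss can transdifferentiate into squamous cell carcinomas (SCC) — an
adeno-to-squamous transdifferentiation (AST) that confers drug resistance.
Viewed through the lens of dynamical systems, AST is a critical transition:
the tumor drifts gradually through the ADC phase, crosses a tipping point,
and then shifts abruptly and irreversibly to the squamous attractor.
Interventions (for example, restoring Wnt/β-catenin signaling) are
effective before the tipping point and largely futile after it, which is
what makes locating the tipping point in time biologically and
therapeutically interesting.

astDNB implements the dynamic network biomarker (DNB) framework for
locating such transitions in serially sampled bulk transcriptomes, along
with the surrounding analyses: PCA trajectories and per-timepoint
dispersion, lineage signature scores (ADC score, SCC score, and their
difference, the AST score), transcription-factor target-overlap tests for
mutual lineage suppression, and cohort incidence summaries. A synthetic
generator plants a known critical transition so every stage can be
validated without access to controlled animal data.

## The DNB model and the composite index

Approaching a bifurcation, a small group of system variables — the dynamic
network biomarker — is expected to satisfy three conditions
simultaneously: its members become strongly correlated with one another,
decouple from the rest of the system, and fluctuate with rising variance.
For a gene module \(M\) evaluated at one time point across replicates:

* \( \mathrm{PCC}_i \): the mean absolute Pearson correlation over
  unordered gene pairs within \(M\);
* \( \mathrm{PCC}_o \): the mean absolute correlation over pairs with one
  gene in \(M\) and one outside;
* \( \mathrm{SD}_i \): the mean across members of the within-timepoint
  standard deviation of normalized log expression.

The composite criticality index combines them:

\[
\mathrm{CI} = \frac{\mathrm{PCC}_i}{\mathrm{PCC}_o} \times \mathrm{SD}_i .
\]

`dnbScan()` evaluates, at every time point, every module produced by
deterministic hierarchical clustering (average linkage on the distance
\(1 - |r|\); every cluster under every merge height with size inside
`[minSize, maxSize]`, default `[5, 200]`, is a candidate). The candidate
with maximal CI is the *dominant module* of that time point, and the time
point whose dominant CI is maximal is reported as the tipping point. All
steps are deterministic: reruns on identical input give identical output.

Key numerical conventions:

* correlations are estimated across replicates, requiring at least 3;
  genes constant across replicates are flagged and assigned correlation 0;
* the \( \mathrm{PCC}_o \) denominator is floored at `epsilon = 1e-6` to
  avoid division blow-up when a module is essentially decoupled;
* CI time-profile ties resolve to the *earliest* time point — the
  conservative call for an early-warning statistic; module-level CI ties
  resolve to the more cohesive module (the detector's output order);
* \( \mathrm{SD}_i \) uses the raw within-timepoint SD by default.
  `sdRelativeToBaseline = TRUE` divides each gene's per-timepoint SD by
  its mean SD across all time points first, which rescales CI profiles
  when genes differ grossly in baseline variability. Either convention is
  defensible; the default is the plainer one and is what all bundled
  validation uses.

The candidate gene subspace is an input: in real analyses one restricts to
genes differential between the two lineages (a few thousand genes).
When no subspace is given, the scan falls back to the `topVariableGenes`
(default 2000) most variable genes.

### Sliding-window variant

With fewer than 3 replicates per time point the correlation step is
undefined. `slidingWindowScan()` pools the replicates of `window`
consecutive time points before estimating correlations and SDs, labeling
each window by its central time point (for an even window, the later of
the two central points). `window = 1` reproduces `dnbScan()` exactly.
Pooling across time converts mean dynamics (e.g. switching lineage
markers) into apparent variance and correlation, which is precisely what
lends the pooled statistic its sensitivity near the transition — but it
also blurs time resolution to roughly the window width, which is why the
per-timepoint scan is preferred whenever replication allows.

## Normalization

Counts are normalized by relative log expression (RLE, median-of-ratios):
each sample's normalization factor is the median, over genes observed in
every sample, of the ratio of the sample's count proportion to the gene's
geometric-mean proportion; factors are rescaled to geometric mean 1 and
multiply the library size. Expression is reported as
\( \log_2(10^6 \cdot c / \text{effective library size} + 1) \) — log2 RPM
with a pseudocount of 1, which keeps zero counts at zero. Genes with a
zero count in any sample are excluded from factor estimation but retained
in the matrix. The normalization is exactly invariant to rescaling any
sample's counts.

## Trajectory and dispersion

`pcaEmbed()` embeds samples on the first two principal components of the
gene-centered log-expression matrix. Genes are centered but not scaled by
default: unit scaling would flatten exactly the high-variance marker genes
whose movement the trajectory is meant to display (`scaleGenes = TRUE` is
available). Components carry a deterministic sign convention (the
largest-magnitude loading of each component is made positive) so
embeddings are reproducible across runs. `timepointDispersion()` measures
pre-transition instability as the mean Euclidean distance of each time
point's samples to their centroid in the 2-D embedding; a singleton time
point has undefined (NA) dispersion. The dispersion is computed on the
visualized plane deliberately — it quantifies the spread the trajectory
plot shows — rather than in the full expression space.

## Signature scores

Two scoring conventions coexist because they answer different questions:

* **Pathway signatures** (`zscoreSignature()`) use the combined-z method:
  each member gene is standardized across samples and the per-sample score
  is the sum of member z-values divided by \( \sqrt{k} \). Under
  independence the score is approximately standard normal, making scores
  comparable across sets of different sizes.
* **Lineage component scores** (`astScore()`) use the plain mean of
  z-values over the ADC-upregulated set and the SCC-upregulated set; the
  AST score is their difference (SCC − ADC). Sorting samples by AST score
  orders a mixed adenosquamous cohort from ADC-like to SCC-like.

Zero-variance genes contribute 0 to either score; standardization is
always across the full cohort supplied. `correlateWithAST()` reports the
signed Pearson correlation of any signature with the AST score, so
"negatively correlated with the AST score" (a signature that decays toward
the squamous state, as Wnt signatures do) reads directly off the result.

The differential gene sets feeding `astScore()` can come from any source.
The bundled `deGenes()` is a deliberately simple stand-in — per-gene Welch
t-tests on normalized log expression with Benjamini–Hochberg adjustment,
gated at fold change > 2 and adjusted p < 0.001 — chosen for transparency
and testability; production analyses may prefer a count-model test and
inject its results as `GeneSet` objects.

## Mutual-suppression TF analysis

`overlapTest()` forms the 2×2 table of two gene sets over an explicit
universe and computes the one-sided (enrichment) hypergeometric tail
probability; enrichment is the scientific claim being tested, though a
two-sided option exists. The universe choice dominates Fisher-type
p-values, so it is an explicit argument everywhere and defaults to the
genes of the supplied expression matrix. The sample odds ratio receives a
0.5 continuity correction only when a table cell is zero, and the result
is flagged when that happens.

`tfEnrichment()` ranks TFs by target enrichment in a query set
(descending −log10 p, ties by overlap then TF id, BH across all TFs).
`buildYinyangNetwork()` asks whether two lineage TF programs counteract
each other: each ADC-family TF is tested against the genes the squamous
program tunes down, each SCC-family TF against the genes the adenomatous
program induces, and a "mutual suppression" verdict requires both pooled
family-level tests to pass `alpha = 0.05` after BH. The construction is
symmetric under exchanging the families with mirrored gene sets. On
independent random programs the verdict fires in well under 5% of
simulations.

## The synthetic generator

`generateTimecourse()` emulates the serial-sampling design the package
targets: seven sampling times (0, 4, 6, 7, 8, 9, 10 weeks), six
replicates each, 600 genes. Its latent layer is Gaussian on the log2
scale; counts are emitted as negative binomial with dispersion 0.1.

* A 30-gene module follows an equicorrelated factor model with
  correlation 0.2 away from the tipping point, rising to 0.85 at the
  planted tipping point (7 weeks), where its standard deviation is also
  multiplied by 3 and its loading on the shared background factor is
  zeroed — realizing all three DNB conditions at once.
* 20 ADC and 20 SCC marker genes switch sigmoidally (time constant 0.35
  weeks, amplitude 3 log2 units — an 8-fold switch completed within about
  one sampling interval), downward and upward respectively; a 15-gene
  Wnt-like panel decays alongside the ADC markers.
* Background genes share a weak tissue factor (pairwise correlation 0.15),
  so the module does not stand out trivially by being the only correlated
  structure.
* Baseline gene means are uniform on 5–9 log2 RPM and the latent
  biological SD is 0.75 log2 units. These two choices place the panel in
  the well-expressed range: DNB candidate subspaces are differential —
  hence expressed — genes, and at lower abundances the log2(RPM + 1)
  floor and count discretization would truncate the inflated-variance
  module at the transition, so the planted correlations would not be
  realized on the observed scale.
* All randomness derives from one root seed; identical configurations
  reproduce bit-identical outputs.

`generateAdscCohort()` models a mixed adenosquamous cohort: each tumor is
a convex mixture of the pure ADC and pure SCC marker profiles at a
per-sample squamous fraction, with the Wnt-like panel decaying as the
fraction grows — the ground truth for AST-score rank-recovery checks.

What the generator does **not** emulate: batch effects, library-type or
GC biases, single-cell structure, gene-length effects, non-equicorrelated
module topologies, and gradual (ramp-like) criticality — the planted
transition is confined to the tipping time point itself. Consequently,
passing recovery tests demonstrates that the estimators detect the
structure they are designed for at realistic noise levels; they do not
demonstrate robustness to confounding that real cohorts may add.

## Validation scale and known limitations

The bundled validation runs at the full default scale (600 genes × 42
samples) over 20 generator seeds for recovery rates, with 200 simulations
for each null calibration and exhaustive small-instance oracles (naive
double-loop CI up to 15 genes; hypergeometric tail summation up to
universe 25) for numerical agreement at 1e-12. These sizes keep the whole
suite under a minute on one core while leaving the recovery statistics
reproducible.

Two limitations are worth stating plainly:

* **Max-CI favors small modules at low replication.** With 6 replicates
  the sampling error of a correlation estimate is large
  (roughly \( (1-\rho^2)/\sqrt{n-1} \approx 0.12 \) at \(\rho = 0.85\)),
  and maximizing CI over all nested clusters selects tight 5–9-gene
  subclusters of the true module: their inflated within-module
  correlation outweighs the slight outside-correlation penalty from the
  module genes they leave behind. The tipping *time* is recovered
  reliably (the SD inflation is shared by every subcluster), but the
  dominant module is typically a high-precision *fragment* of the true
  module rather than the whole of it. Users who want fuller module
  recovery should raise `minSize` toward the expected module scale, pool
  windows to increase the effective sample count, or read the module off
  the full candidate table (`ciTable()`, `moduleTable`) rather than the
  single argmax.
* **Sliding windows blur the transition.** With a transition confined to
  a single time point, every window containing that point carries nearly
  the same pooled signal; with only 2 replicates per time point the scan
  identifies the tipping point most of the time, but adjacent window
  centers are genuinely competitive, and resolution can be no finer than
  the window width.

## Worked example

```{r example, eval = FALSE}
sim <- generateTimecourse(syntheticConfig(seed = 1))
tce <- normalizeRLE(sim$experiment)
prof <- dnbScan(tce)
ciTable(prof)
tippingTime(prof)                  # 7 (weeks)
jac <- length(intersect(dominantModule(prof), sim$truth$moduleGenes)) /
    length(union(dominantModule(prof), sim$truth$moduleGenes))

emb <- pcaEmbed(tce)
timepointDispersion(emb, sim$design)$argmaxTime   # 7 again

cfg <- syntheticConfig(seed = 1)
fr <- runif(50)
coh <- generateAdscCohort(50, fr, cfg)
res <- astScore(coh$expr, geneSet("adc", coh$adcMarkers, "up"),
                geneSet("scc", coh$sccMarkers, "up"))
cor(fr, scores(res$ast), method = "spearman")     # ~0.98
```

The same computations, at the full validation scale, are what
`scripts/acceptance.R` reruns and reports.
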