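# astDNB

Tipping-point analysis of adeno-to-squamous transdifferentiation (AST)
in temporal bulk transcriptomics, built around the dynamic network
biomarker (DNB) framework.

Lung adenocarcinomas (ADC) with combined *KRAS* activation and *LKB1*
loss can switch histology to squamous cell carcinoma (SCC). Treated as a
critical transition of a dynamical system, the switch has a *tipping
point*: before it the tumor state drifts reversibly, after it the
squamous fate is locked in. astDNB locates that tipping point in a
serially sampled RNA-seq time course and provides the surrounding
analyses used to characterize it. It is aimed at computational biologists
analyzing multi-timepoint bulk expression series with replicates —
the bundled synthetic generator means no controlled animal data are
needed to use, test, or extend the method.

## What it computes

For a gene module evaluated at one time point across replicates, with
PCC<sub>i</sub> the mean within-module |Pearson correlation|,
PCC<sub>o</sub> the mean module-to-outside |correlation|, and
SD<sub>i</sub> the mean within-timepoint standard deviation of module
genes, the composite criticality index is

```
CI = (PCC_i / PCC_o) × SD_i
```

A DNB — a module that simultaneously tightens internally, decouples
externally, and fluctuates harder — maximizes CI at the tipping point.
`dnbScan()` builds a correlation network per time point, enumerates
modules by deterministic average-linkage clustering on 1 − |r|, evaluates
CI for each, and reports the time point of maximal dominant CI.
`slidingWindowScan()` pools consecutive time points for sparsely
replicated series.

Around the core scan:

- `normalizeRLE()` — RLE (median-of-ratios) factors, log2(RPM + 1);
- `pcaEmbed()`, `markerOverlay()`, `timepointDispersion()` — trajectory
  and pre-transition instability;
- `zscoreSignature()`, `astScore()`, `correlateWithAST()`, `deGenes()` —
  combined-z pathway scores, ADC/SCC lineage scores, and the AST score
  (SCC − ADC) that orders adenosquamous tumors from ADC-like to SCC-like;
- `overlapTest()`, `tfEnrichment()`, `buildYinyangNetwork()` —
  Fisher-exact TF target overlaps and the mutual-suppression
  ("Yin-Yang") test between lineage TF programs;
- `cohortIncidence()` — SCC incidence summaries from cohort tables;
- `generateTimecourse()`, `generateAdscCohort()` — synthetic data with a
  planted critical transition and known ground truth;
- `runPipeline()` — end-to-end orchestration with a reproducibility
  manifest (a thin CLI lives in `inst/scripts/astdnb-pipeline.R`).

## Worked example

```r
library(astDNB)

sim <- generateTimecourse(syntheticConfig(seed = 1))  # 600 genes, 7 time points x 6 replicates
tce <- normalizeRLE(sim$experiment)
prof <- dnbScan(tce)
prof
#> CIProfile (per_timepoint) over 7 time points
#>   time_weeks pcc_in pcc_out sd_in    ci module_size
#> 1          0 0.9234  0.3665 1.043 2.628           5
#> 2          4 0.9535  0.3698 1.051 2.709           5
#> 3          6 0.9400  0.3894 1.160 2.800           5
#> 4          7 0.9721  0.4031 3.212 7.748           7
#> 5          8 0.9354  0.3574 1.020 2.669           5
#> 6          9 0.9327  0.3530 1.105 2.920           6
#> 7         10 0.9035  0.3653 1.011 2.501           5
#> tipping point: index 4 (7 weeks), dominant module of 7 genes
```

The CI profile is flat until 7 weeks, where the planted DNB module
tightens (PCC<sub>i</sub> 0.97), its variance triples (SD<sub>i</sub>
3.2), and CI spikes to 7.7 — the tipping point, matching the generator's
ground truth (`sim$truth$tStarIndex`). Sample dispersion in the PCA plane
tells the same story:

```r
timepointDispersion(pcaEmbed(tce), sim$design)$dispersion
#>   time_weeks dispersion n
#> 1          0   1.095324 6
#> ...
#> 4          7  14.043367 6      <- maximal spread just before the switch
#> ...
```

On a simulated adenosquamous cohort, the AST score recovers each tumor's
squamous content and a planted Wnt-like signature decays toward the
squamous state:

```r
cfg <- syntheticConfig(seed = 1)
set.seed(7); fr <- runif(50)
coh <- generateAdscCohort(50, fr, cfg)
res <- astScore(coh$expr, geneSet("adc", coh$adcMarkers, "up"),
                geneSet("scc", coh$sccMarkers, "up"))
cor(fr, scores(res$ast), method = "spearman")
#> [1] 0.9888595
correlateWithAST(zscoreSignature(coh$expr, geneSet("Wnt_like", coh$wntMarkers)),
                 res$ast)
#> $r: -0.970   $p: 3.53e-31
```

Cohort incidence from experiment counts:

```r
cohortIncidence(cohortTable(c("KL", "KLC", "KLC_Nkx2-1"),
                            c(24, 12, 12), c(4, 12, 4)))
#>        group n_total n_with_scc incidence_exact incidence_pct
#> 1         KL      24          4        16.66667            17
#> 2        KLC      12         12       100.00000           100
#> 3 KLC_Nkx2-1      12          4        33.33333            33
```

See `vignettes/astDNB-methods.Rmd` for the model, parameter rationale,
and known limitations.

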