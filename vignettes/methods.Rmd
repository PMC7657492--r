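---
title: "Methods: quantifying transcriptome and methylome plasticity of muscle stem cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transcriptome and methylome plasticity of muscle stem cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`MuSCplasticity` analyses a two-factor design on sorted muscle stem cells
(MuSCs): anatomical location (extraocular muscle, EOM, vs *Tibialis
anterior*, TA) crossed with heterotopic transplantation state (pre-graft vs
post-graft, the latter re-isolated from a host TA after regeneration). The
data are a gene-level RNA-seq count matrix and per-sample CpG-level
bisulfite calls, plus interval annotations (H3K27ac peaks, CpG islands,
repeats) and a gene table. This vignette records the models, the parameter
choices and the reasoning behind every decision that the underlying
experiment leaves open.

## Coordinates and containers

Internally all intervals are 1-based closed `GRanges` — the native
Bioconductor convention — and CpG sites are width-1 ranges. BED input and
output (0-based half-open) are converted exactly once, inside `readBed()` /
`writeBed()`; Bismark-style coverage files are read as 1-based positions
with their percent column ignored in favour of the counts (it is recomputed
on write). Methylation and expression matrices are
`SummarizedExperiment` subclasses whose column data *is* the sample sheet:
the sheet is the single source of group membership, and labels
(`EOM`/`TA`, `pre`/`post`) are matched case-sensitively so misgrouping
fails loudly rather than silently.

## Element universe

* **Promoters**: −2000/+500 bp around the TSS in transcription orientation,
  clipped at the chromosome origin. Strand is mandatory because the span is
  asymmetric.
* **CGI promoters**: any promoter sharing ≥ 1 bp with a CpG island.
* **Enhancers**: H3K27ac peaks that do not overlap any promoter. A peak
  overlapping by a single base is removed whole — the definition is a
  peak-level set difference, not a trimming rule — and the output is
  re-checked for promoter overlap on every call.
* **Enhancer–gene links**: each enhancer is assigned the gene whose TSS is
  nearest to the enhancer *midpoint*; beyond 1 Mb an enhancer is left
  unlinked. Midpoint-to-TSS distance was chosen because it is symmetric and
  deterministic where "proximity" alone is ambiguous; exact ties go to the
  lexicographically smallest gene id so reruns are identical. The linker is
  validated against an O(n·m) brute-force search in the test suite.
* **Hox windows**: fixed-width tiles (default 1 kb) across each labelled
  Hox cluster from (min TSS − flank) to (max TSS + flank), flank 5 kb — a
  resolution that shows per-gene structure across a ~100 kb cluster. The
  span is treated half-open, so a 50 kb span tiles into exactly 50 windows.

## Methylation model

A CpG site's methylation is the ratio 100·n_meth/(n_meth+n_unmeth). An
element's methylation is the **unweighted mean of its per-site ratios**:
weighting by read count would let deeply covered sites dominate an element,
coupling the estimate to coverage rather than biology. Two filters mirror
standard practice for shallow bisulfite data from small cell numbers: an
element is quantified in a sample only when **≥ 2 CpGs** are covered, and
retained in an analysis only when quantified in **≥ 3 samples of every
group** being compared.

Per-feature-class landscapes (`featureClassSummary()`) report the genome
as the unweighted mean over *all* covered sites, and every other class as
the distribution of per-element means plus its average. In the synthetic
genome the genome-wide value is therefore a mixture across element classes
(background sites at their own mean, promoters low, repeats high) — the
recovery test compares it against the generator's site-weighted
expectation, not against the background parameter.

### Rolling Z-score

For a contrast A − B, each element contributes Δ(e) = mean_A(e) −
mean_B(e). Because the variance of Δ depends strongly on absolute
methylation (binomial noise is maximal at 50%), Δ is standardised
*locally*: elements are ranked by their two-group mean methylation, and
each element's z-score uses the mean and SD of Δ over the window of the
200 nearest-ranked elements (centred, truncated at the ends of the
ranking). p is the two-sided normal tail; `local_sd = 0` defines z = 0.
The window size, ranking covariate and unadjusted p-values are package
choices — the procedure is named but not parameterised by its source — and
all three are exposed as arguments. Calibration is enforced by test: under
an exchangeable binomial null with 5,000 elements the flag rate at
α = 0.05 must stay within 2.5–7.5%. Note that the element's own Δ is part
of its window, which bounds attainable |z| near √window for a lone
outlier; with the default window of 200 this is immaterial.

### DMRs

Per-site group methylation pools counts across a group's samples (single
shallow samples are too noisy for per-site ratios). Only sites covered in
both groups are eligible. A DMR is a maximal run of consecutive eligible
sites in which every site differs by ≥ 10 percentage points with one sign,
with run length ≥ 5. "More than 5" could also be read strictly; run length
≥ 5 is the default and `strict = TRUE` gives the > 5 reading. The caller
is verified exactly against a brute-force enumeration of all runs on 1,000
random landscapes.

### Graft correction and density shifts

Transplantation itself perturbs both omes, so the homotopic TA arm serves
as its own control: per feature, δ = mean(TA-post) − mean(TA-pre) is
subtracted from **all** post-graft samples. This makes corrected TA-post
group means equal TA-pre means identically; the residual EOM-post signal
is the niche response. For methylation the corrected values are clamped to
[0, 100] by default; `clamp = FALSE` preserves the exact algebraic
identity for verification, and the identity test runs unclamped because
clamping (by design) breaks the algebra for the rare feature pushed out of
range. Features with no TA value in either state are left uncorrected and
counted in a message.

Density-shift tests compare the Δ distribution of a target enhancer set
(e.g. enhancers linked to EOM-specific genes) against a seeded random
subset of background enhancers, size 350, by Welch's two-sample t. The
background is drawn once per comparison with an explicit seed; the test's
type-I rate is checked by simulation (1,000 replicate target draws from a
shared null).

## Expression model

Counts are normalised to log2 RPM: log2(10⁶·c/L + 1), with the +1
pseudocount in RPM units so zero maps to zero. Location DEGs require
|log2 fold change| > 1 **and** Welch p < 0.05 on log2 RPM — the fold-change
gate dominates the call set, which is why a t-test substitute for a
negative-binomial likelihood is acceptable here; exact replication of any
particular DE engine is a non-goal. p-values are deliberately unadjusted
(that is the published criterion); BH-adjusted values are reported
alongside for users. The correction operates on the log scale — the
"expression change" subtracted from post-graft samples is a log2
difference — and classification uses group means of the corrected
post-graft EOM samples, one value per gene.

**Plasticity rescaling**: for a TA-specific gene, score =
100·(x − m_EOM,pre)/(m_TA,pre − m_EOM,pre) with x the corrected EOM-post
mean; EOM-specific genes are rescaled symmetrically. Scores are not
clamped, so a gene that overshoots its donor level goes negative and one
that overshoots the host level exceeds 100. Categories: for TA-specific
genes resistant < 25 ≤ intermediate ≤ 75 < responsive (reversed for
EOM-specific, where low scores mean the gene *reached* the host level).
Boundary scores of exactly 25 or 75 are intermediate — "between" is read
inclusively — and both thresholds are arguments. Genes whose pre-graft
group means coincide have no scale and are skipped with a warning.

## Multivariate views

PCA centres features across samples but does not scale them: percent
methylation and log2 RPM are already on meaningful common scales, and
variance differences between features are signal. Features with any
missing value are dropped (complete-feature filtering, consistent with the
support filters) rather than imputed. Component signs follow a fixed
convention (largest-magnitude loading positive). Sample clustering uses
Euclidean distance between rows of the sample–sample Pearson correlation
matrix with average linkage — a robust default for correlation profiles;
linkage is a package choice. Dendrograms export as Newick via `ape`.

## The synthetic study

`simulationConfig()` encodes the emulated study conditions; all defaults
were fixed from the study design and a priori power reasoning before the
acceptance checks were written, and are not tuned:

* 4 groups (EOM/TA × pre/post) × **10 samples**.
* 3,000 regular genes on four autosomes (50 kb spacing) plus four Hox
  clusters of 10 genes on a fifth chromosome; **261 EOM-specific and 339
  TA-specific DEGs** (13 of the TA set on HoxA/HoxC), effects uniform on
  log2 FC 2–4.
* Negative-binomial counts (size 20) around log-normally drawn baselines,
  library size 5·10⁵; a per-gene N(0, 0.5) log2 graft effect added
  identically to all post-graft samples, so the TA-based correction is
  exactly identifiable.
* Methylation landscape: background sites 50%, promoters 25%, enhancers
  30% (per-element baselines N(30, 10)), CpG islands 5%, repeats 85%;
  Poisson(5) read depth per CpG per sample, so the ≥2-CpG and ≥3-sample
  filters act nontrivially.
* DEG-linked enhancers carry a **25-point** group difference split
  symmetrically (±12.5 around the element baseline, hypomethylated in the
  gene's own location). The size is in line with the large per-enhancer
  differences the assay is meant to capture; the symmetric split keeps the
  two-group mean — the rolling-Z ranking covariate — unshifted, as for any
  purely between-group effect. About 10% of enhancers are planted,
  matching the small fraction of DEG-linked enhancers among all peaks.
* 30 DMRs of 8 consecutive CpGs at ±30 points, in reserved intergenic
  space so no foreign covered site interrupts a run.
* HoxA: TA-high (80%) / EOM-low (20%) across the cluster with post-graft
  EOM at 60% (a planted partial gain); Hox promoters are spared, as for
  protected CGI promoters, which is also what keeps the promoter PCA
  location-blind. Other clusters are flat at 30%.
* A global **+2.6-point** methylation gain in all post-graft samples.
* Plasticity mixtures: EOM-specific 60/30/10 and TA-specific 50/30/20
  responsive/intermediate/resistant; planted Hox DEGs are responsive or
  intermediate only, as genes re-acquiring the host positional code.

Everything derives from one integer seed through per-stage streams, so
datasets are byte-identical across runs and machines. The generator writes
every exchange format plus a ground-truth JSON.

What the generator does **not** emulate — and what passing tests therefore
do not certify on real data: read-level artefacts (mapping, bisulfite
conversion error, PCR duplicates), biological covariance between
neighbouring elements, donor effects (samples are exchangeable within
group), overdispersion of methylation beyond binomial, partial or variable
graft effects across samples, and annotation error in peaks or TSSs.

## Problem sizes and verification

The shipped test suite and acceptance script run the full default study
(3,040 genes, ~141,000 CpGs × 40 samples, ~5,600 enhancers) in about a
minute, plus oracle and calibration checks: DMR caller vs brute force on
1,000 random landscapes, linking vs brute force on 10,000 intervals,
rolling-Z and density-shift null rates on 5,000 features (1,000 replicate
draws for the density test), and exact correction/rescaling identities at
1e-9. These sizes were chosen as the smallest at which the planted effects
are comfortably identifiable, keeping iteration fast.

## Known limitations

* The rolling-Z window and ranking covariate are heuristic; a beta-binomial
  or smoothing-based DM test is out of scope by design.
* The DE test is a Welch t on log2 RPM, not a count likelihood; with n = 10
  per group and FC > 2 gating this is adequate, but at small n it will be
  conservative.
* The graft correction assumes the transplantation effect is additive and
  shared between EOM and TA cells; a muscle-specific graft response would
  be absorbed into the plasticity signal.
* Enhancer–gene assignment by nearest TSS is a proximity heuristic;
  long-range or skipped-gene regulation is not modelled.
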