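---
title: "Methods: scoring and testing rRNA 2'-O-methylation plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and testing rRNA 2'-O-methylation plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

Ribose 2'-O-methylation protects the phosphodiester bond immediately 3' of
the modified nucleotide from alkaline hydrolysis. In RiboMeth-seq, total RNA
is randomly fragmented under alkaline conditions and sequenced, and the
number of fragment ends mapping to each bond is counted. At a methylated
site the end count drops in proportion to the fraction of molecules carrying
the methyl group, while the neighbouring bonds cleave at the background
rate. Everything in this package starts from such per-position end-count
tables; read trimming and alignment are upstream and out of scope.

`ribomethr` indexes bonds 1..L-1 on each mature rRNA species (18S, 1869 nt;
5.8S, 157 nt; 28S, 5070 nt), with the bond protected by methylation of
nucleotide p being bond p. On disk, profiles are bedGraph-like TSVs of 5'
end counts; the reader attributes the 5'-end count at position i+1 to bond
i (`end_convention = "five_prime"`, the default; `"three_prime"` and
`"both"` are available because library chemistries differ in which end they
preserve).

## The RMS score

For a catalogued site with bond count $n_{site}$ and eligible flanking
bonds within $\pm w$ positions (default $w = 2$),

$$\mathrm{score} = \mathrm{clip}\left(1 - \frac{n_{site}}{\bar n_{flank}},\ 0,\ 1\right),$$

where $\bar n_{flank}$ is the arithmetic mean of the flank counts. The
score estimates the methylated fraction: 0 means unmethylated, 1 fully
methylated. Design choices worth knowing:

* **Flank exclusion.** Flanking bonds that are themselves catalogued sites
  are excluded, so clustered sites (the catalog contains pairs closer than
  2w) do not deflate each other's local baseline.
* **Coverage masking.** If the flank mean falls below `min_flank_mean`
  (default 10 counts) the score is reported missing rather than noisy; the
  same applies when the window would run past a reference end. Masked cells
  carry `valid = FALSE` and are imputed (by site mean) only where a
  complete matrix is unavoidable, i.e. before embedding.
* **Replicate handling.** Technical replicates are merged by summing
  counts before scoring — summing is exactly equivalent to scoring the
  pooled cleavage evidence and uses the Poisson nature of the counts,
  whereas averaging scores would weight shallow replicates equally.
* **Scale invariance.** The score depends only on the local count ratio,
  so library-size normalisation is unnecessary.

The window, threshold and end convention are exposed in `ScoreParams`-style
arguments because the scoring variant used by any particular lab differs in
exactly these knobs.

## Donor-blocked differential testing

The default study design is 3 donors x 3 growth states (proliferating P,
contact-inhibited quiescent Q, peroxide-induced senescent SIPS) x 2
technical replicates, i.e. 9 biological samples after merging. Donor
identity is a strong batch factor in primary-cell data, so state effects
are tested per site with the additive fixed-effects model

$$y_{ds} = \mu + \alpha_d + \beta_s + \varepsilon_{ds},$$

and $F = MS_{state}/MS_{residual}$ with $(a-1)$ and $(n-a-b+1)$ degrees of
freedom. Only complete balanced crossings are fitted (for the default
design: 2 and 4 df); unbalanced tables are rejected rather than silently
switching sums-of-squares conventions, and sites with empty cells are
skipped with a reason. Degenerate tables get explicit answers: zero
residual variance with a real effect reports p = 0 and a `zero_residual`
flag; no variance at all reports F = 0, p = 1.

P-values are adjusted with Benjamini–Hochberg (`bh_adjust()`, a thin
wrapper over `stats::p.adjust` that propagates missing values), and the
discovery cutoff defaults to q < 0.1. Pairwise state contrasts use the
Tukey studentized-range statistic computed from the blocked model's
residual mean square, $q = |\bar y_u - \bar y_v| / \sqrt{MS_{res}/n}$,
against the range distribution with the blocked residual df — the post-hoc
is only meaningful where the omnibus q passes. Sites are then classified
as `variable` (q below cutoff), `constitutive_high` (stable, grand mean
score > 0.9) or `substoichiometric_stable`.

## Embedding and factor elimination

"Eliminating" the donor factor before visualisation is implemented as
per-site subtraction of the donor mean (adding back the site grand mean),
the exact analogue of the donor term in the ANOVA; the operation is
idempotent and mask-preserving. Embedding uses exact t-SNE (`Rtsne` with
`theta = 0`) on the samples-by-sites matrix, with a PCA fallback for very
small n. At n = 9 the usual perplexity heuristics are inapplicable: the
affinity calibration requires 3 * perplexity < n - 1, so the requested
perplexity (default 3) is clamped to (n - 2)/3. Coordinates are
deterministic for a fixed seed, which is recorded in the result.

`silhouette_optimal_k()` scans seeded k-means partitions of the 2-D
coordinates and returns the k with the highest mean silhouette width (ties
to smaller k). Following the conventional silhouette reading, a best mean
width below 0.5 is flagged as weak structure: compact random noise
routinely reaches widths near 0.4-0.5 under k-means, so "there are k
clusters" should not be concluded from such values.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
the scale of the default design:

* **Truth.** Per-site methylated fraction
  `m = clip(base + donor_offset + state_offset, 0, 1)`. The default preset
  uses base 0.97 at 95 of the 104 catalogued sites and substoichiometric
  bases (0.60-0.90) at nine variable sites, with planted state offsets of
  0.04-0.10; exactly three of the nine (LSU-A2388, LSU-G3723, LSU-G4588)
  differ between Q and SIPS. Donor offsets are drawn once per (site,
  donor) from Normal(0, `donor_sd`), default 0.01. State offsets are fixed
  rather than random so planted truth is unambiguous; the additive (not
  logit) scale is adequate for effects ≤ 0.15 around these bases.
* **Counts.** Each bond fires `Poisson(depth_per_bond * (1 - m * protection))`
  independently per library; defaults 3000 events per bond, protection 1.
  There is no fragment-length model: the wet protocol's 20-40 nt size
  selection is assumed not to bias per-bond end frequencies, which is the
  level the scoring operates on.
* **Donor-dominant variant.** With `donor_sd = 0.01` the planted state
  effects, concentrated in nine sites, outweigh donor scatter across 104
  sites, so raw-score embeddings organise by state. Donor-led structure —
  the regime where batch-factor elimination is interesting — requires the
  donor signature across all sites to exceed the planted state separation
  (about 0.2 in Euclidean norm here); `senescence_preset(donor_sd = 0.04)`
  is the documented configuration for that regime, and is what the
  clustering validation uses.
* **Side channels.** Guide-snoRNA expression is simulated per biological
  sample as `coupling * m + (1 - coupling) * baseline + noise` (defaults
  0.9 / 0.8 / sd 0.01), reflecting the observation that methylation at
  substoichiometric sites tracks its guide's abundance. Northern band
  intensities are state means times unit-mean lognormal noise with a given
  CV; the default means place the 30S:41S precursor ratio at double its
  P-state value in Q and SIPS.

What the generator does **not** emulate: sequence- or GC-dependent cleavage
bias, read-level artefacts (the simulation starts at bond counts),
partially overlapping modification types, correlated donor effects across
sites, or heavy-tailed count overdispersion. Passing the planted-truth
checks therefore demonstrates the statistical machinery is correct, not
that real libraries are free of those artefacts.

## Problem sizes and numerical choices

Validation runs use the full 104-site catalog with the 3x3x2 design
(127k Poisson draws per dataset), 2000 single-site null tables for type-I
calibration, and 200 replicates of the 104-site planted-truth layout for
FDR behaviour — all sized to run in minutes on one core. Sums of squares
within 1e-12 of the site's total are treated as exactly zero when flagging
degenerate fits; Ct-based quantification fixes amplification efficiency at
2; one-sample t-tests run on linear-scale P-normalised values (the scale
on which "expected value 1" is stated), and a zero-variance sample is an
explicit error rather than an infinite statistic. Guide groups that one
assay cannot resolve (SNORD88A/B/C) are treated as a single aggregate
expression series.

## Bundled catalog caveat

Only eleven site coordinates in the bundled 104-site catalog are
documented positions (see the fixture header); the remainder are
deterministic placeholders that give the pipeline a realistic site count
and spacing. Analyses of real data should supply a curated catalog via
`load_site_catalog(path)`.

## A minimal session

```{r}
library(ribomethr)

res <- run_full_pipeline(default_run_config(out_dir = "rms_demo", seed = 1))
tidy(res$diff)                       # per-site F/p/q, Tukey p, classification
glance(res$diff)
autoplot(res$diff)
autoplot(res$embedding_adjusted, design = res$design)
```
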