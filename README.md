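# ribomethr

Quantify ribose 2'-O-methylation (2'-O-Me) of human ribosomal RNA from
RiboMeth-seq end-count profiles, and test whether methylation at individual
sites changes between cellular growth states.

## The problem

2'-O-Me is the most abundant modification of human rRNA (about a hundred
catalogued sites, each installed by a box C/D snoRNP whose SNORD guide
base-pairs with the target). The methyl group protects the phosphodiester
bond 3' of the modified nucleotide from alkaline hydrolysis, so after random
alkaline fragmentation and sequencing, the fragment-end count at that bond
drops in proportion to the fraction of molecules methylated there.
`ribomethr` is for groups profiling that stoichiometry across conditions —
for example primary fibroblasts from several donors in proliferating (P),
quiescent (Q) and stress-induced senescent (SIPS) states — where donor
identity is a batch factor that must be blocked before state effects can be
seen.

The per-site **RMS score** is the flank-normalised protection

```
score = clip(1 - n_site / mean(n_flank), 0, 1)      # 0 = unmethylated, 1 = fully methylated
```

with flanks taken ±2 bonds (catalogued neighbours excluded) and scores
masked below a coverage threshold. State effects are tested per site with a
donor-blocked two-factor ANOVA, `score ~ donor + state`, using
`F = MS_state / MS_residual`; p-values are Benjamini–Hochberg adjusted
(discovery at q < 0.1) and pairwise state contrasts use Tukey's studentized
range on the blocked residual. Samples can be embedded in 2-D (exact t-SNE)
before and after donor-mean elimination, and site methylation can be related
to guide-snoRNA expression (ΔΔCt qPCR, northern blots) and to pre-rRNA
processing ratios (47S:28S, 30S:41S, ...) with one-sample t-tests against 1.

A bundled generator produces ground-truthed synthetic datasets (Poisson
cleavage counts with methylation-dependent protection, donor offsets,
planted state effects at nine substoichiometric sites, technical
replicates), so every stage is validated against known truth. See the
methods vignette (`vignettes/ribomethr-methods.Rmd`) for the model details
and the generator's scope.

## Worked example

```r
library(ribomethr)

res <- run_full_pipeline(default_run_config(out_dir = "rms_demo", seed = 1))
res$diff
#> Differential rRNA 2'-O-methylation analysis
#>   sites tested: 104 of 104
#>   q cutoff: 0.1  high-methylation cutoff: 0.9
#>   constitutive_high: 94
#>   variable: 10

dplyr::filter(tidy(res$diff), classification == "variable")
#>    label     mean_P mean_Q mean_SIPS F_state  q_state p_tukey_Q-SIPS
#>  1 SSU-G436   0.650  0.730     0.735   158.  0.00233       0.596
#>  2 SSU-C797   0.594  0.704     0.701   245.  0.00170       0.833
#>  3 SSU-A858   0.970  0.972     0.969    31.9 0.0363        0.00300
#>  4 SSU-G867   0.740  0.801     0.799    45.7 0.0203        0.933
#>  5 SSU-C1272  0.800  0.856     0.854   259.  0.00170       0.617
#>  6 LSU-G1303  0.721  0.787     0.793    88.8 0.00631       0.623
#>  7 LSU-A2388  0.731  0.761     0.821   953.  0.000456      0.0000269
#>  8 LSU-G2411  0.753  0.812     0.811   193.  0.00218       0.983
#>  9 LSU-G3723  0.551  0.640     0.709   158.  0.00233       0.00333
#> 10 LSU-G4588  0.817  0.881     0.926   271.  0.00170       0.00143
```

This simulated run plants state effects at nine substoichiometric sites;
all nine are recovered at q < 0.1 (SSU-A858 is the run's one false
positive — its state means are flat and its Tukey p reflects noise), the
P state is hypomethylated at most of them, and only LSU-A2388, LSU-G3723
and LSU-G4588 separate Q from SIPS (`p_tukey_Q-SIPS < 0.05`). Donor-mean
elimination changes what the embedding shows: clustering quality then
favours the three growth states,

```r
as.integer(silhouette_optimal_k(res$embedding_adjusted))
#> [1] 3
autoplot(res$embedding_adjusted, design = res$design)
```

All artifacts (score table, per-site test results, embeddings, correlation
and ratio tables, YAML manifest with seed and config hash) are written
under `rms_demo/`. A thin command-line wrapper with `simulate`, `score`,
`diff`, `correlate`, `ratios` and `all` subcommands is installed at
`inst/cli/rms-pipeline`.

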