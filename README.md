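# posenrich

13C-positional enrichment analysis for GC-EI-MS measurements of TMS
(trimethylsilyl) derivatives of amino and organic acids.

## What it does, and for whom

Stable-isotope labeling experiments read out on GC-MS as carbon isotopologue
distributions (CIDs): per mass fragment, the fractions of molecules carrying
0..n extra 13C within the fragment's n backbone carbons. For questions about
plant central metabolism — photorespiratory serine production, PEPc vs. TCA
cycle contributions to malate and glutamate — the *position* of the label
matters, not just the count. Because EI fragmentation of a TMS derivative
yields several fragments retaining known backbone subsets, and a fragment's
fractional mean 13C enrichment is the mean of the per-position enrichments
over the carbons it retains,

```
E(C1C2C3) = (p1 + p2 + p3)/3,  E(C2C3) = (p2 + p3)/2
=>  p1 = 3·E(C1C2C3) − 2·E(C2C3)
```

positional enrichments can be computed as linear combinations of fragment
mean enrichments. The package provides, for alanine, glycine, serine,
proline, glutamate and malate (2TMS/3TMS derivatives):

* a curated fragment registry (formulas, M0 m/z, carbon backbones) with a
  mass-consistency audit;
* correction of raw isotopic-cluster areas for naturally occurring isotopes
  of all elements except the backbone carbons — optionally also for backbone
  natural 13C abundance and tracer isotopic purity (0.99) — via a correction
  matrix solved by non-negative least squares, yielding
  `isotopologue_fraction` and `mean_enrichment`;
* the published positional combinations, verified symbolically and tagged
  with their validation verdict (validated: glycine C1/C2, serine C1/C2/C3,
  malate C1, glutamate C1 via m/z 246), plus a generic least-squares solver
  with identifiability reporting;
* a 13C-PT standard validation framework (binomial CIDs at p = 0.5, Pascal
  rescaling, 95%-CI bias flags, per-fragment/per-combination verdict reports);
* a forward simulator (PT standards, light/dark tracer kinetics, co-eluting
  contaminant ions, multiplicative noise) that makes every stage testable
  without instrument data;
* an end-to-end pipeline reading per-sample `Name`/`Area` tables, with
  two-sided Wilcoxon–Mann–Whitney light/dark comparisons, and a thin CLI
  (`inst/cli/posenrich.R`: simulate / correct / positions / validate /
  compare).

Intended users: plant metabolism and 13C-fluxomics groups running
low-resolution GC-EI-MS labeling experiments.

## Worked example

```r
library(posenrich)

# registry audit: exactly the two documented inconsistent rows
validate_fragment_table()
#> # A tibble: 2 × 6
#>   fragment_id          formula_published m0_published m0_computed formula_working m0_working
#> 1 Glutamate_C2C3C4C5_… C10H24NO2Si2               245         246 C10H24NO2Si2          246
#> 2 Proline_C2C3C4C5_142 C7H16N                     142         114 C7H16NSi              142

# simulate noiseless binomial 13C-PT standards and run the PT-mode pipeline
pt  <- simulate_pt_standard_dataset(n_replicates = 4, noise_cv = 0)
res <- run_pipeline(pt, pipeline_config(correct_backbone = FALSE, compare = FALSE))
range(res$enrichments$mean_enrichment)
#> [1] 0.5 0.5
val <- subset(res$positional, validated & nchar(position) == 2)
range(val$value)
#> [1] 0.5 0.5
```

Every fragment of a PT standard must read a fractional mean enrichment of
exactly 0.5, and every validated positional combination must return 0.5
(50%); deviations under noise or injected contaminants quantify measurement
bias and its propagation into the positional calculations (see
`validation_report()` and the vignette in `vignettes/`).

## Acceptance script

`scripts/acceptance.R` recomputes the workflow's reference quantities from
scratch with the installed package — PT-standard fragment enrichment
recovery, the 0%/100% full-correction endpoints at tracer purity 0.99 (in
percent), and the validated positional enrichments on simulated PT standards
(in percent) — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
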