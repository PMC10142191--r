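---
title: "Measuring 13C-positional enrichments from GC-MS TMS fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 13C-positional enrichments from GC-MS TMS fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(posenrich)
```

## The problem

Low-resolution GC-EI-MS separates the molecules of a metabolite by total mass,
so a 13C-labeling experiment yields, per mass fragment, a carbon isotopologue
distribution (CID): the fractions of molecules carrying 0..n extra mass units
within the fragment's n backbone carbons. Isotopologues do not say *where* the
label sits. However, electron-impact fragmentation of trimethylsilyl (TMS)
derivatives produces several fragments per derivative, each retaining a known
subset of the metabolite's backbone carbons. Because a fragment's fractional
mean 13C enrichment is the arithmetic mean of the per-position enrichments
over the carbons it retains, fragments that share part of the backbone can be
combined linearly to isolate single positions — for a 3-carbon metabolite X:

$$ E_{C1C2C3} = \tfrac{1}{3}(p_1 + p_2 + p_3), \qquad
   E_{C2C3} = \tfrac{1}{2}(p_2 + p_3) \implies
   p_1 = 3\,E_{C1C2C3} - 2\,E_{C2C3}. $$

Positional enrichments localize fluxes that isotopologues cannot: the
photorespiratory GDC/SHMT step places label on serine C2; PEPc activity and
the TCA cycle place label on the C1 of malate and glutamate.

The catch is that these combinations amplify measurement bias: weights like
(+5, −4) multiply a small fragment-level inaccuracy several-fold. The package
therefore couples the calculation machinery with a validation framework based
on tailor-made 13C-PT standards and with a forward simulator that can inject
the documented classes of analytical bias.

## The correction model

Raw cluster areas at M0..Mn mix the backbone-carbon labeling signal with the
natural isotopes of every other atom (TMS groups contribute C, H and
especially Si, whose +1/+2 isotopes are abundant). `build_correction_matrix()`
predicts, for each pure j-labeled isotopologue, the measured cluster pattern:

* the convolution of the natural isotope distributions of all atoms
  *except* the n backbone carbons (always applied);
* optionally (`correct_backbone = TRUE`, for tracer experiments): a
  Binomial(j, purity) term for the j tracer-labeled carbons (a tracer carbon
  is 12C with probability 1 − purity, default purity 0.99) and a
  Binomial(n − j, 0.011) term for natural 13C on the n − j unlabeled carbons.
  With this full correction, natural-abundance material reads exactly 0% and
  maximally labeled material reads exactly 100% enrichment.

13C-PT standards already hold a fully controlled 12C/13C backbone, so they are
corrected in the first mode only. The two backbone corrections are applied
together or not at all: they describe one physical situation (a tracer
experiment), and applying one without the other has no interpretation.

`correct_areas()` solves `raw = M cid` by non-negative least squares
(Lawson–Hanson active set, written here because no installed package provides
NNLS) and renormalizes; plain inversion can return negative fractions on
noisy clusters. The relative residual is recorded: a large residual is the
main symptom of a co-eluting contaminant, and the pipeline warns above
`residual_warn` (default 1e-3, calibrated for clean synthetic data — raise it
for noisy real data where the expected residual is of the order of the area
CV). Mean enrichment is `sum(i * Mi) / n`.

### Numerical choices

* Cluster window: exactly n+1 masses M0..Mn. Longer input clusters are
  rejected, not silently truncated.
* Isotope table: 13C defaults to 0.011 (1.1%), overridable; H/N/O/Si use
  standard terrestrial abundances (Si 0.9223/0.0467/0.0310). Only the 13C
  value is prescribed by the method; the others are package defaults.
* Out-of-range positional values (possible once fragment biases propagate)
  are flagged, never clipped.
* No normalization to the t = 0 time point is ever applied: fragments with
  poor accuracy at natural abundance would distort the normalization scale
  differently for different fragments of the same derivative.

## The fragment registry

`load_fragment_table()` ships the curated fragments of the six metabolites
(alanine, glycine, serine, proline, glutamate, malate — 2TMS/3TMS
derivatives), each with elemental formula, M0 m/z and backbone-carbon subset,
keyed as `"<Metabolite>_<positions>_<M0>"`. Two published rows are not
mass-consistent and are kept verbatim for audit next to a corrected working
pair: the proline C2-C3-C4-C5 fragment at m/z 142 (published formula C7H16N
computes 114; the working formula C7H16NSi equals the derivative mass 259
minus the TMS-CO2 loss 117) and the glutamate C2-C3-C4-C5 fragment (published
m/z 245 vs. its formula's 246; the working M0 is 246, the value used when the
fragment is named in combinations). `validate_fragment_table()` recomputes all
masses and reports exactly these discrepancies:

```{r}
validate_fragment_table()
```

A glycine C2 fragment at m/z 174 (loss of TMS-CO2 from the 3TMS derivative,
C7H20NSi2) is included in addition to the published table because the glycine
positional combinations use it.

## Positional combinations

`published_combinations()` returns every route used for the six metabolites,
expressed as flattened linear weights over fragment enrichments and verified
*symbolically at construction*: the weighted sum of the fragments'
mean-of-positions rows must equal the target position's unit row exactly.
Routes that the 13C-PT evaluation validated are tagged `validated = TRUE`:
glycine C1 and C2, serine C1/C2/C3 (both method A, based on the C2 fragment,
and method B, based on the C1C2C3 fragment), malate C1 (via m/z 335 or 245)
and glutamate C1 via the m/z 246 fragment. Known-biased routes (alanine C2/C3,
proline C1, malate C3/C4, glutamate C1 via m/z 156 or measured directly at
m/z 117) are shipped too, tagged `FALSE`, so bias propagation can be studied.

Three printed equations in the source method are typographically corrupted
and are implemented in their algebraically consistent form (each is forced by
the mean-of-positions model): the serine method-B C1/C3 lines (swapped
labels), its third line (C2 = 2E(C2C3) + 2E(C1C2) − 3E(C1C2C3)), and the
malate C3C4 intermediate (E(C3C4) = (3E(C2C3C4) − E(C2))/2). The two
published malate C3 routes that substitute the *calculated* C1 and C4 flatten
to the same functional, 2E(C2C3) − E(C2), and are kept under one method tag;
the route through the C3C4 intermediate uses the directly *measured* C4
fragment and remains distinct. Replicates are always combined *after* the
positional calculation (one value per replicate, then mean ± SD), never by
combining averaged enrichments.

`solve_positions_generic()` generalizes the hand-derived combinations: it
solves the mean-of-positions system by least squares for any fragment set and
reports which positions are identifiable (unit vector in the row space). On
exactly determined sets it reproduces the published combinations.

## Validation with 13C-PT standards

A 13C-PT standard labels every carbon independently with probability 0.5, so
every n-carbon fragment has the binomial CID C(n,i)/2^n (Pascal's-triangle row
after rescaling by 2^n), a mean enrichment of exactly 0.5, and every
positional combination must return 0.5. `validation_report()` compares
measured (or simulated) standards against these expectations per
isotopologue, per fragment and per combination, flagging values whose 95%
confidence interval (mean ± 1.96 SD/√k, sample SD with k − 1 denominator — the
method states the 1.96 factor, not a t quantile, and is reproduced verbatim)
excludes the expectation. A 1e-9 absolute tolerance is added to the interval
so the degenerate zero-width CI of noiseless synthetic replicates does not
flag floating-point rounding; real biases are orders of magnitude larger.

## The simulator: what it emulates, and what it does not

`simulate_pt_standard_dataset()` and `simulate_labeling_kinetics()` generate
raw Name/Area tables by running the correction model *forward*: fragment CIDs
from ground-truth labeling states (Poisson-binomial for independent
per-position probabilities, marginalization for explicit isotopomer
distributions), untruncated cluster patterns including the purity and
natural-abundance terms in tracer mode, optional contaminant ions with their
own natural-isotope clusters, and multiplicative log-normal noise of stated
CV (mean-preserving). Defaults are the stated experimental design: 4
replicates; PT standards noiseless by default; kinetics noise CV 0.05, a
typical GC-MS between-replicate area CV.

The default kinetics scenario encodes the qualitative biology the method is
used to detect, with exponential-saturation ramps over t = 0, 1, 2, 4, 6 h
(plateaus chosen once as realistic mid-range enrichments): serine labeled
only at C2 in the light (plateau 0.30) and unlabeled in the dark; glycine C2
likewise (0.32); glutamate C2–C5 labeled under both conditions (0.18) with C1
labeling only in the dark (0.14, the cyclic-TCA signature); malate C1 equal
across conditions (0.12) and C4 higher in light (PEPc). All states are zero
at t = 0.

Because the simulator inverts exactly the model the correction assumes, a
green roundtrip test establishes internal consistency — that correction,
combination algebra and statistics are implemented correctly — not that the
model captures every property of real chromatograms. Real-data effects that
are deliberately *not* simulated: chromatographic peak shape and co-elution
dynamics, detector saturation, derivatization artifacts, and the unexplained
magnitude of some published biases (e.g. a malate C2-C3 fragment reading 0.36
at natural abundance); contaminant injections reproduce the *direction* and
propagation of such biases, with user-set intensities.

## Statistics on labeling experiments

When samples span two conditions, `run_pipeline()` compares them per time
point and per fragment/position with a two-sided Wilcoxon–Mann–Whitney test:
exact p-values for groups of up to 8 without ties, mid-rank normal
approximation otherwise (the 8-sample switch is a package decision). A
Shapiro–Wilk p-value is logged per group as the rationale for the
nonparametric choice; the rank-sum test is always the one used. No
multiple-testing correction is applied, matching the source procedure —
users needing control should apply it downstream.

## Worked example

```{r example, eval = FALSE}
# simulate noiseless PT standards, correct, validate
samples <- simulate_pt_standard_dataset(n_replicates = 4, noise_cv = 0)
report <- validation_report(samples)
report # zero flags on clean input

# a tracer kinetics experiment with light/dark comparison
kin <- simulate_labeling_kinetics(n_replicates = 4, noise_cv = 0.02, seed = 7)
res <- run_pipeline(kin, pipeline_config(correct_backbone = TRUE,
                                         residual_warn = Inf))
subset(res$comparisons, level == "position" & metabolite == "Serine" &
         time_h == 6)
```

## Known limitations

* Low-resolution (nominal-mass) correction only; isobaric contaminants within
  the cluster window are inseparable by design and must be caught by the
  PT-standard validation instead.
* The registry covers the six metabolites above; users can extend it via
  `fragment_definition()` / `read_fragment_tsv()`, but new fragments need
  independent confirmation of their carbon backbone.
* Positional estimates inherit the mean-of-positions assumption; fragments
  whose formation discriminates isotopomers (fragmentation isotope effects)
  would violate it.
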