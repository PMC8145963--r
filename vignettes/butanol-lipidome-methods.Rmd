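---
title: "Methods: species-level lipidomics of solvent-stressed E. coli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-level lipidomics of solvent-stressed E. coli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colipidr)
```

This vignette explains the models behind `colipidr`, the parameters
that matter, the design choices made where the design was genuinely
open, and what the synthetic-study tests do and do not demonstrate
about real data.

## The measurement model

HILIC chromatography separates phospholipids by headgroup, so in a
~5-minute gradient the retention time of a feature encodes its lipid
*class*, while the m/z of the deprotonated ion [M−H]⁻ encodes its
species-level identity: class plus total acyl carbons and total double
bonds (e.g. PE 34:1). Individual chains and their positions are not
resolved — this is species-level lipidomics, and everything downstream
respects that granularity.

The in-silico database enumerates (class, carbons, double bonds,
cyclopropane) combinations per class, with elemental formulas built as

    species = backbone + acyl chains (as free fatty acids) − one H2O per linkage,

where the combined acyl contribution for C carbons and m = DB + rings
modifications over n chains is C~C~H~2C−2m~O~2n~. Backbones are encoded
as class data (a table in `R/lipid-classes.R`) and verified in the test
suite against an independent structure-assembly oracle that builds each
formula from glycerol, phosphoric acid, headgroup and fatty-acid
components. A cyclopropane ring costs two hydrogens, exactly like a
double bond, so PE 33:0c1 and PE 33:1 share one formula and one mass.

**Isobar convention.** Because rings and double bonds are isobaric, the
database carries both annotations as distinct rows sharing one m/z and
marks one *canonical*: odd total carbons take the cyclopropane name,
even totals the double-bond name. The biology behind the convention:
Cfa synthesizes rings by adding a methylene across a double bond, so
ring-carrying species have odd carbon totals in a background of
even-chain fatty acids. Chromatographic evidence could override this in
real data; the annotator exposes the full database so users can
re-resolve.

**Isotope model.** De-isotoping uses a carbon-only binomial model at
¹³C natural abundance p = 1.1% (configurable): the A+k isotopologue is
`choose(n, k) (p/(1−p))^k` relative to the monoisotopic peak.
Contributions of ²H, ¹⁵N, ¹⁷O and ¹⁸O are below 0.1% at A+2 for these
formulas and are ignored. Within a class, species two double-bond
equivalents apart differ by 2.0157 Th while the A+2 satellite sits
2.0067 Th up — merged at unit resolution — so the correction subtracts,
in a single ascending-m/z pass per class, each species' predicted A+2
from its heavier neighbour, using already-corrected upstream
intensities, clipping at zero. A+1 satellites fall at odd nominal-mass
offsets, never on another species, which the test suite checks by
construction of the database. The correction assumes envelopes are
physically present; applying it to data synthesized without envelopes
over-subtracts, which is why `annotate_lipidome(correct_isotopes =
FALSE)` exists for that degenerate case.

## Key parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `mz_tolerance` | 0.3 | Th | unit-resolution ion trap; half the 1-Th spacing with margin |
| retention windows | class table | min | artifact convention for a ~5-min HILIC gradient; annotator and simulator share it |
| `p13c` | 0.011 | — | ¹³C natural abundance |
| noise filter | 3 × noise floor, ≥ 1 sample | counts | floor = median positive intensity of unmatched features, excluding unmatched ¹³C satellites (which carry real signal) |
| `window`, `conf` (ANOVA) | 101, 5 | species, pseudo-obs | screening-study settings for the regularized test |
| `window_points` (growth) | 11 (55 min) | readings | see below |
| `od_floor`, `min_od` | 0.02, 0.2 | OD600 | inoculum level; viability bar for lipidome inclusion |

**Growth window width.** The maximum specific growth rate is the
largest least-squares slope of ln OD over a sliding window. On logistic
curves the window trades bias for variance: a 1-h window saturates on
fast cultures (µ ≈ 1.2 h⁻¹ under-estimated by ~5%), very short windows
inflate the noise-driven maximum. Calibration on noiseless and
1%-noise logistic curves over µ ∈ [0.3, 1.2] h⁻¹ put the best
compromise at 11 points (55 min on the 5-min grid), which recovers 95%+
of curves within 5% relative error; the width is a parameter and is
reported alongside every fit.

**Regularized ANOVA.** With k groups, N samples and pooled
within-group variance s² on df~w~ = N − k degrees of freedom, the
test statistic uses

    s²_reg = (conf · s²_bg + df_w · s²) / (conf + df_w)

with denominator degrees of freedom conf + df~w~, where s²_bg is the
mean pooled variance over a `window`-species sliding window in
mean-abundance rank. `conf` acts as that many pseudo-observations of
the background variance. This form reduces *exactly* to the classical
one-way ANOVA at conf = 0 (a property the tests verify against
`stats::aov`), while stabilizing triplicate designs at conf = 5. Null
simulations (identical group means) give uniform p-values by a KS
check. Significance is the Benjamini–Hochberg adjusted p below 0.05; a
posterior-probability (PPDE-style) post-processing could be plugged in
where the adjustment happens, but BH is well defined and is the
default.

**Z-scores** read the butanol group against the control distribution,
`(x̄_but − x̄_ctl)/s_ctl`, positive meaning higher under butanol. A
species absent in every control culture has zero control variance and
its Z is reported missing rather than infinite — the
phosphatidylbutanol case.

**Acyl properties** are chain-weighted: a cardiolipin contributes four
chains per mole, a headgroup acylate three, so with
w~i~ = percent~i~ × n~chains,i~ the mean chain length is
Σ w~i~(C~i~/n~i~)/Σ w~i~, and analogously for double bonds and rings.
Mole weighting is available via a flag; the absolute values depend on
this choice (and on per-species ionization efficiency, which percent
normalization does not remove), so cross-condition *differences* are
the meaningful readout.

## The synthetic study generator

`simulate_study()` emulates the screen the analysis targets: 116 gene
constructs (knock-outs and overexpressors drawn from a lipid-gene
pool), both ± 0.5% butanol arms, triplicate cultures, wild-type and
empty-vector controls replicated across 96-well plates (~730
lipidomes), ~230 species over 11 classes with baseline abundances
spanning ~25% down to 0.01% (class weights × per-chain carbon bell ×
per-modification decay, roughened by a Dirichlet draw).

Planted structure, all recorded in the ground-truth ledger:

* **Markers.** Ten species (abundant PEs, cyclopropane PGs, headgroup
  acylates, PBut) form the marker panel. Every lipid gene reports on a
  pair of markers with a fixed fold change (e^1.3 ≈ 3.7, matching the
  10–30× construct ranges such screens report) whose direction flips
  between overexpression and knock-out; sign patterns are unique per
  reporter pair, and marker effects redistribute abundance within the
  marker pool so the signature lives in marker ratios. Markers respond
  to constructs through this map alone — the planted panel *is* the
  discriminative signal.
* **Curated biology.** cfa scales cyclopropane species (×3.5 OV, ×0.08
  KO) with inverse effects on their unsaturated precursors; fabH tilts
  chain length and unsaturation along its expression gradient; aas,
  clsA, clsB and pldA scale their product classes; glpD/glpK/glpR are
  growth-only. Butanol multiplies µ by 0.5, reduces cyclopropane
  species (×0.6, precursors rising), and induces PBut — but only in
  ClsB overexpressors, whose phospholipase-D-type headgroup exchange
  transfers phosphatidyl groups onto medium butanol.
* **Measurement.** Intensities get 2% multiplicative noise (the
  replicate spread reported for percent-normalized screens of this
  kind: an abundant marker at 25.9 ± 0.5%), features carry m/z and
  retention jitter, full isotope envelopes, a per-cell detection limit
  (exercising forced integration) and ~0.2 unassignable decoy features
  per real species. Growth is logistic on a 5-min grid over 16 h with
  1% OD noise; 1% of cultures fail (stay below the OD 0.2 QC bar).

What the generator does **not** emulate: chromatographic peak shapes
and co-elution, ionization-efficiency differences between species,
in-source fragmentation, retention drift between batches, or biological
co-regulation beyond the planted blocks. Passing the round-trip and
recovery tests therefore shows the *pipeline's* correctness under the
stated error model, not robustness to every pathology of real LC-MS
data.

## Marker selection: panel size and stability

Backward elimination tracks out-of-bag error while repeatedly dropping
the least important feature (10% of the remainder per step by default).
Two panel rules are provided. The default returns the smallest panel
within one standard error of the minimum OOB error. Because percent
compositions are closed, marker information is partly redundant — on
some data sets a 5-species panel genuinely attains the tolerance
criterion, and the OOB-optimal size fluctuates. The fixed-size rule
(`panel_size = 10`) instead returns the features that survive
elimination longest, which is the stable, screening-style way to
compare against a reference panel: across forest seeds the recovered
planted-marker core is identical, while one or two interchangeable
members of correlated clusters rotate through the remaining slots
(pairwise panel Jaccard 0.67–0.82). Users comparing panels between
studies should compare the fixed-size form.

## Numerical choices and degenerate inputs

* Normalization divides by the exact column total, so columns sum to
  100 to machine precision; all-zero samples (e.g. cell-free blanks)
  are dropped with a log entry.
* Force-integration fills truly absent cells with 0, not an imputed
  noise draw, so downstream statistics see true sparsity; provenance
  flags (`detected` / `force_integrated`) let users re-impute.
* Constant species are excluded from correlation clustering (undefined
  r) and logged; leaf order is made deterministic by sorting species
  alphabetically before clustering.
* Tag counting keeps the top-k and bottom-k construct sets disjoint
  when ties (many zero-abundance constructs) would overlap them.
* Welch tests with fewer than two replicates return `ns` with an
  explicit flag rather than an error.
* Growth fits require a full window of consecutive readings above the
  OD floor; cultures that never clear it get a missing µ and fail QC
  downstream.

## Problem sizes used by the tests

The test and acceptance suites run scaled studies — 16–24 constructs,
three replicates, 4–6 control replicates (~100–170 samples) and
100-tree forests — which preserve the full design's structure
(both construct types, both butanol arms, plate-replicated controls,
the complete species set). Growth recovery uses 200 simulated curves;
null calibration uses 200 species. These sizes were chosen as the
smallest at which the planted effects are comfortably detectable, so
the checks measure correctness rather than raw power.

## Known limitations

* Species-level only: no acyl positions, no MS/MS evidence; isobar
  resolution relies on the odd/even-carbon convention.
* Percent-of-total normalization is compositional; correlations on
  percent values can carry closure-induced dependence. Spearman
  correlation is available, and effect interpretation should focus on
  ratios and differences, not absolute percentages.
* The de-isotoping correction addresses A+2 carbon overlap only, which
  is exact for this database's spacing but would need extension for
  classes with other inter-species gaps.
* Doubly charged cardiolipin and PGP ions are out of scope; all ions
  are treated as singly deprotonated.
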