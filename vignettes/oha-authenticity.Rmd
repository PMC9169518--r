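---
title: "OHA profiling and purity models for citrus juice authenticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OHA profiling and purity models for citrus juice authenticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citrusOHA)
```

## The problem

Sweet orange and grapefruit juices command higher prices than mandarin
and pomelo juices, and the cheaper juices are chemically and
organoleptically close enough that moderate undeclared blending (above
the ~10 % that labelling rules tolerate) is hard to detect. Oxygenated
heterocyclic aglycones — methoxyflavones (MFs), coumarins, and
furanocoumarins (FCs) — are secondary metabolites whose accumulation is
strongly species-specific, so the quantitative OHA profile of a juice
carries a fingerprint of its botanical origin. `citrusOHA` turns that
fingerprint into a purity estimate and a three-way verdict
(authentic / indeterminate / fraudulent).

This vignette documents the models, the tunable parameters, the
synthetic-data generator the test-suite runs on, and the numerical
choices made where the design was genuinely open.

## Identification model

A sample peak is matched against a catalog record by three independent
gates, all of which must pass, and the match must be unique:

* **Full-spectrum conformity.** Both spectra (UV 210–400 nm; emission
  340–560 nm under 340 nm excitation) are linearly resampled to the
  common 1-nm grid of their overlapping support, max-normalised, and
  scored by Pearson correlation clipped to [0, 1]. Defaults: UV
  conformity ≥ 0.99, emission conformity ≥ 0.98 (applied only when both
  peak and standard fluoresce; a fluorescence mismatch — one side dark,
  the other emitting — is itself disqualifying, since 5-hydroxylation
  quenches emission and is diagnostic).
* **Fluorescence peak-height ratio.** The ratio of the highest to the
  second-highest response among the monitored 400/450/500 nm emission
  channels, with ties broken toward the shorter wavelength. The
  candidate must reproduce the catalogued wavelength pair and match the
  ratio within 25 % relative.
* **Retention index.** Van den Dool/Kratz-style bracketed linear
  interpolation on the C8–C14 alkylarylketone ladder,
  `RI = 100·n + 100·(rt − t_n)/(t_{n+1} − t_n)`, with index 100×carbon
  number at each anchor. Extrapolation is refused: peaks eluting before
  propiophenone (C8) carry `NA` and the RI gate is skipped for them.
  Default window |ΔRI| ≤ 15, spanning the rounding noise of printed
  index tables.

Ambiguity (two or more records passing every gate) yields *no match*
rather than a best match: a doubtful identity must not feed the
authenticity models. All four thresholds are configurable through
`match_gates()`.

The `backfit_anchor_bracket()` helper addresses a practical situation:
published (Rt, RI) pairs from one bracket are available but the ketone
ladder itself is not. A least-squares line RI ~ Rt, inverted at
RI = 100·n, recovers surrogate anchor times that reproduce held-out
published indices at integer precision.

### Spectral screening rules

`classify_spectrum()` encodes the empirical spectra→structure rules for
peaks that match no standard. Landmarks use ±7 nm windows; the
decisive cues are: FCs show a dominant shoulder near 250 nm
(mono-substituted) or 270 nm (5,8-disubstituted) beside a weaker main
band in 305–320 nm; coumarins are read from their longest-wavelength UV
band against the emission maximum (≈395 nm for 7-OR, ≈461 nm for
7-hydroxylated, ≈422 nm for 6,7-diOR, ≈437 nm with a double shoulder
below 263 nm for 5,7-diOR); MFs show one (4′-OMe) or two (3′,4′-diOMe)
shoulders in 240–280 nm; 5-hydroxylation red-shifts the UV spectrum and
quenches emission in both families. Within the ±7 nm rubric, three
boundaries had to be drawn more finely so that all thirteen packaged
candidate rows (including the deliberately uncategorized one) separate:
the 5-OR,7-OH window is confined to main 327–335 nm, the 7-OH window to
320–326 nm, and the MF fallback requires a main band at ≥ 332 nm.
Spectra matching no rule are reported `"uncategorized C"`/`"uncategorized
FC"` rather than forced into a class.

## Quantitation model

Calibration is **through the origin** (the catalog stores slopes only),
fitted by least squares with R² measured against the mean response. The
linear range is established top-down: while R² < 0.999 and more than
five levels remain, the highest level is dropped. LOD and LOQ follow the
S/N = 3 and 10 definitions (`3σ/slope`, `10σ/slope`).

A juice concentration is `area / slope × IS-ratio / 9`: the
internal-standard ratio (nominal/observed psoralen response, spiked at
5 mg/L) corrects multiplicative detector drift, and the factor 9
(configurable) undoes the 9-fold SPE enrichment of the extract.
Below-LOQ results are **kept with a flag** rather than zeroed or
LOQ/2-substituted — trace detections are informative for profiling —
while below-LOD results become 0 at matrix assembly. Screened candidates
carry no mg/L calibration and are propagated as response peak areas;
autoscaling downstream makes the unit difference immaterial, and a
per-column `value_kind` audit trail is preserved.

## Chemometrics

All multivariate steps run on mean-centred, autoscaled data; constant
columns are dropped explicitly. PCA is a thin wrapper over the singular
value decomposition. PLS1 uses sequential latent-variable extraction
(weights `X'y/|X'y|`, least-squares loadings, deflation of both blocks;
the y-deflation is numerically immaterial for PLS1 but fixed for
reproducibility), with coefficients composed as `B = W(P'W)⁻¹q`.

**Full cross-validation** is interpreted as leave-one-out, the standard
meaning in chemometrics software; k-segment (consecutive or seeded
random) validation is available. The suggested component count is the
RMSECV minimum relaxed toward fewer components by a one-standard-error
rule, with the SE of the RMSECV obtained by the delta method from the
per-sample squared errors. On pure-noise responses this reduces to one
component.

**Martens' uncertainty test** measures each variable's stability as the
spread of its coefficient over the cross-validation submodels around the
full-model value, `s²_b = Σ_m (b_m − b)²·(M−1)/M` (the (M−1)/M jackknife
convention), and declares a variable significant at the 5 % level when
`b ± t(0.975, M−1)·s_b` excludes zero. `reduce_variables()` composes
cross-validation, component selection and the uncertainty test, returning
survivors ordered by |coefficient|; the sign encodes the marker
direction. Coefficients are reported in autoscaled space and labelled as
such.

## Authenticity models

Virtual blends are purity-weighted averages of two pure-juice profiles,
`x = p/100·main + (1−p/100)·adulterant`, generated exhaustively over all
main × adulterant cultivar-average pairs at each purity level. Training
levels are 95/90/80 % for the orange-vs-mandarin scenario (plus pure
orange at 100 and pure mandarin at 0 — the mandarin cloud anchors the
low end of the purity axis) and 90/80 % plus pure grapefruit for the two
grapefruit-vs-pomelo scenarios, which published no 0 % level; the pure
adulterant rows are controlled by a flag. Predicted purity is reported
**unclipped** — values above 100 % or below 0 % are legitimate outputs
for samples outside the training cloud — and the decision rules operate
on the raw value:

| scenario | authentic (PP ≥) | fraudulent (PP <) |
|---|---|---|
| orange vs mandarin | 94 % | 82 % |
| grapefruit vs Shatianyou pomelo | 94 % | 85 % |
| grapefruit vs Wendan pomelo | 95 % | 87 % |

Between the bounds the verdict is *indeterminate*: additional analytical
evidence is required. When the pomelo subgroup is unknown, both
grapefruit models run and the worst verdict is kept
(`classify_grapefruit_conservative()`), avoiding false authentication.

Test sets mirror the training purity levels but are built from
cultivar-disjoint profiles; the provenance table of every blend set
records the parent profiles and purity of each row, and blend rows
reconstruct from provenance to machine precision.

## The synthetic-data generator

No instrument data ships with the package; the generator produces
everything the pipeline consumes.

* **Species templates** (`inst/extdata/species_templates.csv`) give
  per-compound mean concentrations (mg/L of juice; response areas for
  uncalibrated candidates) for orange, mandarin, grapefruit and the two
  pomelo subgroups. Magnitudes are this package's own synthetic
  choices, constrained by three published anchors: expected totals fall
  in the per-species ranges (orange < 5 mg/L, mandarin 5–10 mg/L,
  grapefruit/pomelo 5–100 mg/L); hot-spot sets follow the species
  profiles (orange rich in sinensetin, hexamethyl-O-quercetagetin,
  tetramethyl-O-scutellarein and heptamethoxyflavone; mandarin in
  isosinensetin, tangeretin, nobiletin and their 5-OH/demethyl
  relatives); and scenario markers separate main species from
  adulterant in the direction the chemistry dictates — the epoxides
  meranzin and 6′,7′-epoxybergamottin, stable in the near-neutral
  Shatianyou juice, mark SG pomelo, while the acid-stable bergaptol,
  isomeranzin and 6′,7′-dihydroxybergamottin mark the sour Wendan
  group.
* **Cultivar variability** is lognormal per compound with expectation
  equal to the template mean and coefficient of variation
  `cv × cv_scale`. The default cv is 0.25, chosen so that the synthetic
  90 %-purity cluster separates from the pure-juice cluster while the
  held-out RMSEP stays in the low single digits — the qualitative
  behaviour reported for the real data. `cv_scale` raises the
  dispersion of the secondary MFs (nobiletin,
  tetramethyl-O-isoscutellarein, 5-demethylnobiletin,
  5-demethyltangeretin and relatives), reflecting the strong
  cultivar-to-cultivar variation of those compounds in mandarin
  germplasm; this is what makes the jackknife test retire them in
  favour of the three stable markers. Draws are independent across
  compounds by default — no covariance information is published — and a
  `correlation` parameter adds a shared per-cultivar lognormal factor
  for robustness studies.
* **Chromatogram simulation** inverts the quantitation model: one peak
  per non-zero compound at the catalogued retention time (plus seeded
  jitter), quant-channel area `concentration × 9 × slope`, remaining UV
  channels shaped by the compound's modelled spectrum, fluorescence
  heights reproducing the catalogued peak-height ratio, plus a psoralen
  IS peak. A multiplicative response drift applies to all peaks and is
  cancelled by the IS correction. At zero noise the
  identify-then-quantify round trip recovers the generating profile to
  1e-6 relative, and identification recovers all 52 catalog identities.
* **Anchor ladder.** The default C8–C14 retention times (8.60, 16.91,
  26.20, 36.20, 38.22, 42.35, 47.35 min) were solved so bracketed
  interpolation reproduces the catalogued candidate retention indices
  within about one index unit; the first candidate elutes before C8 and
  correctly receives no index.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: co-elution and peak-purity artefacts,
matrix effects and non-linear detector response, covariance structure
among compounds beyond the optional shared factor, harvest-year and
processing effects, and the true per-compound concentration scales of
real cultivars (only species totals and qualitative hot-spot patterns
are anchored). Synthetic model performance close to the published
figures is a consistency check of the machinery, not a validation on
real juice.

## Catalog provenance

The packaged catalog (`inst/extdata/oha_catalog.csv`) mixes two kinds of
content: calibration blocks for the 39 quantified compounds and the
complete rows of the 13 screened candidates follow the published tables
(one printed fluorescence R² of 0.9986 is accepted by the loader, which
requires R² to round to ≥ 0.999 at three decimals; freshly fitted
calibrations enforce the bound exactly); the retention times, spectral
maxima, emission maxima and fluorescence ratios of the 39 knowns are
**synthetic placeholders**, generated from the family spectral rules so
that the identification round trip is exact and all 52 records are
mutually distinguishable under the default gates. They are adequate for
simulation and testing, not reference values for real instruments.

## Problem sizes and numerical choices

The test-suite and the acceptance script run at deliberately moderate
sizes: purity studies use 20 training and 10 held-out cultivars per
species (320-row test sets), the headline figure is the median RMSEP
over ten seeds, property suites use 100 random matrices of up to 10 × 4,
and the Monte-Carlo check of the lognormal parameterisation uses 1000
draws. Key tolerances: score orthogonality and oracle agreement at
1e-8; blend conservation at 1e-12; zero-noise recovery at 1e-6;
autoscaling round-trip at 1e-12. Ties in the fluorescence ratio break
toward the shorter wavelength; constant columns abort autoscaling with
an explicit record rather than silently passing through.

## Limitations

* Decision thresholds are fixed published constants; they are not
  re-estimated from data, and nothing here constitutes a regulatory
  determination.
* PLS1 only — no PLS2, O-PLS or kernel variants; no peak picking from
  raw detector streams; no mass-spectral identification.
* The correction-factor (CF) columns of the catalog are stored verbatim
  but unused: their published semantics are not derivable from the
  printed values, and the internal-standard ratio correction is applied
  instead.
* Multi-adulterant (three-way) mixtures are out of scope; each model
  assumes a single adulterant species.
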