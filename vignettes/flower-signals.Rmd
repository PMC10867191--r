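---
title: "Modelling flower colour signals for bee vision along elevational gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flower colour signals for bee vision along elevational gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexaflora)
```

## The scientific question

Flowering-plant communities advertise to pollinators through colour,
achromatic contrast and size. Bees use these channels differently:
detection at a distance relies on the green-receptor (achromatic)
channel, close-range recognition on trichromatic colour vision. If
abiotic conditions become harsher with altitude while pollinators grow
scarcer, the community-level distribution of these signals should shift
along an elevational gradient. `hexaflora` provides the machinery for
asking that question quantitatively: a receptor-level visual model that
converts reflectance spectra into a chromatic statistic (colour
contrast, cc) and an achromatic one (green contrast, gc), and
phylogenetically informed regressions relating them to each other and
to flower size within elevational zones.

## The visual model and its assumptions

The hexagon colour space for trichromatic hymenopteran vision assumes
(i) photon catches integrated linearly over 300–700 nm, (ii) complete
von Kries adaptation to a green-foliage background under daylight, and
(iii) a saturating transduction $E = P/(P+1)$ per receptor. Under these
assumptions the adaptation background sits exactly at the hexagon
centre with $E = 0.5$ in every receptor, which the package enforces as
an exact fixed point (a unit test asserts cc = gc = 0 for the
background to machine precision). Adaptation also makes every locus
invariant to rescaling the illuminant, a property tested to 1e-9.

Shipped standard curves:

* **Illuminant** — CIE D65 tabulated at 10 nm, linearly interpolated
  and converted to relative quanta (energy × wavelength). Only relative
  shape matters, by the invariance above.
* **Background** — a smooth parametric green-leaf curve (low UV, a
  chlorophyll bump near 550 nm, a red-edge onset near 700 nm). It is
  synthetic, not a measurement; users with a measured local foliage
  spectrum can substitute it by building `standard_curves()` by hand.
* **Receptor sensitivities** — rhodopsin-nomogram (Govardovskii A1)
  templates at honeybee literature peaks 344, 436, 544 nm, normalised
  to 1. The UV beta-band pulls the realised argmax a couple of
  nanometres below the nominal alpha-band peak; this is a property of
  the template, not an error.

Tunable parameters that matter: the **achromatic-region radius**
(default 0.11 hexagon units, a common behavioural discrimination
threshold; only the `achromatic` flag depends on it), and the
**wavelength grid** (default 300–700 nm at 1 nm). Integration uses the
trapezoid rule on that grid; against a 0.1 nm quadrature the catches
agree to better than 1e-6, far below spectrometer noise. Hexagon
sectors are the standard six 60° wedges with the pure-UV direction at
the $E_{UV}$ vertex.

Replicate flowers (3–5 per species) are averaged **as spectra before
visual modelling** by default. Because the model is nonlinear, this is
not identical to modelling each replicate and averaging the hexagon
loci; the alternative order is available as
`run_pipeline(config = list(average_loci = TRUE))`. At realistic
replicate noise the two orders agree to well under 0.01 in cc and gc
(tested), so the choice is immaterial in practice; averaging spectra
first was chosen because it matches how spectral libraries are usually
curated.

Negative reflectance (instrument noise near the dark reference) is
clipped to zero with a warning; values above 1 are kept, since
exceeding a white standard is physical for glossy petals.

## Phylogenetic regressions

All comparative statistics are built on the lambda transform of the
Brownian covariance $C$ of the tree ($C_{ij}$ = shared root-to-MRCA
path length): $V(\lambda) = \lambda C + (1-\lambda)\,\mathrm{diag}(C)$.
Writing $D = \mathrm{diag}(C)$ and eigendecomposing
$D^{-1/2} C D^{-1/2} - I = Q \Lambda Q'$ once per tree, every GLS
quantity at any $\lambda$ reduces to weighted least squares with
weights $1/(1+\lambda \Lambda_i)$. This makes the profile likelihood
essentially free after one $O(n^3)$ decomposition, and gives
`lambda_max` — the largest $\lambda$ keeping $V$ positive definite — in
closed form from the most negative eigenvalue. Polytomies need no
special handling: shared-path covariance is defined for any rooted
tree, so unresolved nodes are never randomly resolved.

Estimation choices:

* **ML, not REML**, for $\lambda$ in both regression and single-trait
  use, matching the defaults of the standard comparative-regression
  implementations.
* **Search bounds**: $[0, 1]$ for regressions (the convention of PGLS
  software), but $[0, \lambda_{max}]$ for single-trait signal
  estimation (the convention of phylogenetic-signal software, which is
  why single-trait estimates slightly above 1 can occur on trees that
  allow them). Each fitted model reports its own $\lambda$; when two
  predictors are modelled for the same zone the estimates can differ,
  and no attempt is made to force a single joint value.
* **Optimizer**: 32-point grid pre-scan over the bounds followed by
  golden-section refinement in the bracketing interval, tolerance 1e-6
  in $\lambda$. The pre-scan guards against local optima in the
  profile.
* **Confidence interval** for $\lambda$: profile likelihood at the
  $\chi^2_1$ 95% cutoff, truncated at the search bounds.
* **Inference**: coefficient SEs use the unbiased residual variance;
  t tests have $n - p$ degrees of freedom. AIC counts the $\beta$s,
  $\sigma^2$ and $\lambda$ as parameters. Adjusted $R^2$ compares
  whitened residual sums of squares against an intercept-only GLS fit
  at the same $\lambda$.
* **Model set** per zone: gc ~ cc (linear), gc ~ cc² + cc (quadratic),
  gc ~ log(cc) (natural log; base is a convention choice — the fit and
  its p-value are invariant to it, only the coefficient scale
  changes), plus gc ~ size. A predictor equal to zero under the log
  model is an error, never silently offset.
* **Selection**: AIC ascending; models within 2 AIC units of the best
  are treated as tied and the tie goes to the higher adjusted $R^2$
  (first-listed on exact equality).
* **Signal test**: likelihood ratio of $\hat\lambda$ against
  $\lambda = 0$, $p = P(\chi^2_1 \ge 2\Delta\ln L)$. Because
  $\hat\lambda$ is boundary-constrained at 0, the test is conservative
  under the null — observed type-I rates in the validation suite run
  well below 5%.

Correctness is anchored three ways: at $\lambda = 0$ (or on a star
tree) fits equal OLS to 1e-8; at fixed $\lambda$ they equal the direct
matrix GLS formula on random instances; and with ML $\lambda$ they
match `nlme::gls(corPagel)` and `phytools::phylosig` on simulated data.

## Elevational zones and summaries

Zones follow the five-band vegetation scheme: Foothills [0, 500),
Submontane [500, 1500), Montane [1500, 2500), Upper-montane
[2500, 3000), Alpine [3000, ∞) m a.s.l., assigned from the mean of
each species' reported elevational range. The published band labels
leave the metre at 3,000 ambiguous; half-open bins with 3,000 m in
Alpine guarantee every species exactly one zone.

The "most frequently observed" value of a continuous signal is
estimated as the peak of a Gaussian kernel density (Silverman
bandwidth, 512 grid points over the data range) — a definition choice,
since modes of continuous data are otherwise ill-defined. Modes require
at least 3 species; constant samples short-circuit to the constant.
Zone means carry t-based 95% CIs. PGLS fits are attempted only for
zones with at least `min_zone_n` (default 10) species.

## The synthetic-data generator

`sim_dataset()` produces inputs with the statistical structure the
analysis assumes, so every stage is testable end to end without
downloads. Defaults describe the community shape this pipeline targets:

* **714 species** split over the five zones in proportions
  183/258/170/67/36 — the observed distribution of a large island
  flora across its vegetation zones.
* **Tree**: Yule, rescaled to unit height, with 20% of internal
  non-root nodes collapsed into polytomies by pushing their parent-edge
  lengths onto their children (root-to-tip distances, and hence the
  Brownian covariance, are preserved exactly; the tree remains
  ultrametric).
* **Colour contrast**: lambda-transformed Brownian motion
  ($\lambda = 0.5$ by default, mid-range of the per-zone estimates such
  analyses report) squashed into $(0, 0.65)$ by a logistic with unit
  slope, so that with unit Brownian rate the central 95% of values stay
  clear of both bounds.
* **Green contrast**: $0.22 + 0.22\,cc$ plus lambda-structured noise
  (marginal sd 0.03), clipped to $[0, 0.5]$. The defaults keep gc below
  ≈0.42, which is the ceiling reachable by physically plausible bright
  flowers (reflectance ≤ 1.2) against the shipped foliage background;
  clipping therefore essentially never binds and slope recovery is
  unbiased.
* **Size**: log-normal with meanlog declining linearly in elevation
  (−9 × 10⁻⁵ log-mm per metre — about 14.5 mm at sea level to 10–11 mm
  at 3,300 m), sdlog 0.45.
* **Spectra**: each species' curve is the foliage background scaled in
  brightness and multiplied by one minus an absorption feature (a
  Gaussian UV/blue band, or a sigmoidal short-wavelength cut-off for
  strongly chromatic targets). Brightness and absorption depth are
  found by bounded 2-D search so that the curve, run through the
  package's own visual model, reproduces the species' target cc and gc
  (bright branch, $E_G = 0.5 + gc$); residual design error is
  typically below 1e-4 and species exceeding the 0.02 tolerance after
  five random feature placements are flagged. Replicates (3–5) are
  perturbed multiplicatively by smooth Gaussian-process noise (length
  scale 50 nm, relative sd 2%), mimicking the smooth
  illumination/geometry differences between real replicate
  measurements rather than white noise.

What the generator does **not** emulate: instrument artefacts (dark
drift, stray light), discrete pigment classes and their characteristic
spectral shapes, zone-dependent regression structure, correlation
between size and colour signals, or sampling unevenness within zones.
Passing end-to-end tests therefore demonstrates that the pipeline
recovers known generating structure through all of its stages — not
that any particular ecological conclusion holds for real floras.

## Validation problem sizes

The validation suite exercises: exact hexagon closed forms; equivalence
of PGLS with OLS and with the direct GLS matrix formula; recovery of
$\lambda \in \{0, 0.5, 1\}$ on 300-tip trees (100 replicates each,
mean absolute error < 0.1, type-I rate of the signal LRT ≤ 10%); AIC
selection of a strongly quadratic generator at n = 200 (≥ 90% of 100
replicates); and a full simulate → write → read → analyse round trip at
n = 300 checking zone accounting and coefficient recovery within
Monte-Carlo intervals. These sizes were chosen as the smallest at which
the asymptotic behaviour being claimed is already visible.

## Known limitations

* The hexagon model is honeybee-specific; fly-vision colour models and
  receptor-noise-limited models are out of scope.
* Single-predictor PGLS only; no multivariate response, measurement
  error model, or Ornstein–Uhlenbeck alternative (and no Blomberg's K).
* The λ profile CI is truncated at the search bounds; for estimates at
  a bound the interval endpoint is the bound itself.
* The foliage background and illuminant are canonical curves; analyses
  of habitats with unusual backgrounds should supply measured ones.
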