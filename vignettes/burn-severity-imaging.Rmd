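---
title: "Methods: hemoglobin-parameter estimation and burn-severity imaging from RGB images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemoglobin-parameter estimation and burn-severity imaging from RGB images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

An RGB photograph of skin carries three numbers per pixel, yet the visible
diffuse reflectance of skin is shaped by four chromophores: melanin in the
epidermis and oxygenated hemoglobin (HbO), deoxygenated hemoglobin (HbR) and
methemoglobin (metHb) in the dermal blood. In thermally injured tissue the
hemoglobin pool reorganizes — total hemoglobin CHbT, tissue oxygen
saturation StO2 = 100·CHbO/CHbT and methemoglobin saturation
StMet = 100·CmetHb/CHbT all shift with burn depth — so maps of these
parameters are a basis for classifying burn severity noninvasively.
`burnchrom` implements the full chain: a physics-based forward model of skin
reflectance, a colorimetric bridge from spectra to camera values, an
empirical regression inverse from tristimulus values to chromophore
concentrations, and a canonical discriminant classifier on the derived
hemoglobin parameters.

## Forward model: two-layer white Monte Carlo

Skin is modeled as an epidermis of 0.06 mm over a dermis of 4.94 mm, both
with refractive index 1.4 under air. The diffuse reflectance at each
wavelength factorizes over layers into path-length distributions attenuated
by Beer–Lambert absorption: if $P(\mu_s', l)$ is the distribution of photon
path length $l$ accumulated in a layer, then

$$\Theta = \Big[\textstyle\int P_e(\mu_{s,e}', l_e)\,
  e^{-\mu_{a,m} l_e}\, dl\Big] \times
  \Big[\textstyle\int P_d(\mu_{s,d}', l_d)\,
  e^{-(\mu_{a,HbO}+\mu_{a,HbR}+\mu_{a,metHb}) l_d}\, dl\Big].$$

Because the path-length distributions depend only on scattering, one
zero-absorption ("white") Monte Carlo run per wavelength suffices: each
detected photon's per-layer path lengths $(l_e, l_d)$ are recorded, and any
absorption combination is evaluated afterwards by reweighting,
$\Theta = \frac{1}{N}\sum_i w_i\, e^{-\mu_{a,e} l_{e,i} - \mu_{a,d} l_{d,i}}$.
This makes the 1550-combination training set essentially free once the 31
scattering runs exist, and it makes $\partial\Theta/\partial\mu_a \le 0$ and
$\Theta \in [0, 1]$ exact properties of the estimator rather than sampling
accidents.

Numerical choices, made once:

* **Scattering model.** Only the reduced scattering coefficient
  $\mu_s'(\lambda) = 2\times10^5\lambda^{-1.5} + 2\times10^{12}\lambda^{-4}$
  is specified, so transport uses isotropic scattering with
  $\mu_s = \mu_s'$ (similarity relation, $g = 0$); any $(\mu_s, g)$ pair
  with the same $\mu_s'$ is equivalent at the level of diffuse reflectance.
  The power law's units are not stated alongside the formula; we read its
  output as cm⁻¹, giving 10.3 mm⁻¹ at 400 nm falling to 1.9 mm⁻¹ at
  700 nm — the physiological range for skin (a mm⁻¹ reading would give an
  unphysical 103 mm⁻¹ at 400 nm). The convention is recorded on the
  returned object and can be overridden.
* **Detection.** Photons are launched as a collimated pencil beam at normal
  incidence; every photon exiting the top surface counts as diffuse
  reflectance regardless of exit position or angle. The specular entry
  reflection (2.8% at normal incidence for n = 1.4) is excluded from the
  diffuse channel, emulating the crossed-polarizer rejection of specular
  reflection in the imaging geometry.
* **Boundaries.** The air/tissue interface applies Fresnel
  reflection/transmission probabilistically (total internal reflection
  beyond ~45.6°); the epidermis–dermis interface is index-matched so no
  Fresnel event occurs there; photons crossing the dermis bottom are
  recorded as transmitted and discarded (the 5-mm slab geometry; a
  semi-infinite dermis would raise red-region reflectance slightly).
* **Photon budget.** Default 10⁵ photons per wavelength (configurable).
  Because the white-MC table is reused across all absorption combinations,
  Monte Carlo noise enters only through the 31 scattering runs; we verified
  that the in-silico validation statistics are unchanged at 4×10⁵ photons
  and across LUT seeds, so 10⁵ is not a limiting choice.
* **RNG.** A xoshiro256+ generator seeded per wavelength from one root
  integer makes every table bit-reproducible independent of R's RNG state.
* **Roulette.** Weight roulette (threshold 10⁻⁴, survival 0.1) applies only
  to the direct-absorption oracle, where weights decay by continuous
  Beer–Lambert attenuation along each substep; in the white run weights
  never fall below launch weight.

The direct-absorption simulator (`simulate_reflectance_direct`) exists only
as an independent oracle: the test suite requires white-MC reweighting and
direct transport to agree within 3 combined standard errors on randomized
two-layer models.

## Optical properties

Chromophore spectra are bundled as versioned CSVs with a provenance
manifest. Oxy- and deoxyhemoglobin molar extinction coefficients are the
standard literature compilation on the tetramer basis (64,500 g/mol),
tabulated at the 31 grid points; whole blood with 2.32 mM hemoglobin
(hematocrit 45%) defines the 100 vol.% reference, so a dermal blood volume
fraction of $C$ vol.% at saturations (StO2, StMet) contributes molar
concentrations $(C/100)\cdot 2.32\,\mathrm{mM}$ split by saturation
fractions, with the deoxygenated fraction $1 - (StO2+StMet)/100$.
Conversion to absorption uses $\mu_a = \ln(10)\,\varepsilon\,C$ for decadic
$\varepsilon$. The methemoglobin spectrum is a synthetic landmark
interpolation of the published aquomet curves (Soret near 405 nm, the
500-nm band, the characteristic 630-nm band) — flagged as synthetic in the
manifest because no verbatim tabulation was available to bundle — and the
melanosome spectrum uses the standard power-law approximation
$519 \cdot (\lambda/500)^{-3.48}$ cm⁻¹, scaled linearly by the melanin
volume fraction. Requests outside the bundled 400–700 nm grid are rejected
rather than extrapolated.

## Colorimetry

Reflectance spectra are integrated to CIEXYZ tristimulus values by discrete
summation at the 10-nm grid, $X = k\sum E\bar{x}\Theta$ (likewise Y, Z)
with $k = 100/\sum E\bar{y}$, which pins Y = 100 for the perfect diffuser
under any illuminant — an exact normalization the tests assert for both
bundled illuminants. The training illuminant is not specified by the
source method; we default to CIE D65 (CIE 1931 2° observer functions,
bundled at 10-nm steps) and enforce at run time that training and
estimation use the same illuminant. A comparison under illuminant E moved
the validation correlations by under 0.01, so the choice is not critical.
The camera path (`calibrate_n1`) fits the 3×3 RGB→XYZ map by least squares
over a 24-chip chart; in-silico work bypasses the camera entirely and
operates in XYZ.

## The regression inverse

The inverse map is four independent ordinary-least-squares regressions of
the chromophore concentrations on the ten quadratic monomials
$(1, X, Y, Z, X^2, Y^2, Z^2, XY, XZ, YZ)$, packed as the 4×10 matrix N2
acting on the feature column vector (the shape consistent with applying it
to a 10-vector, although it is sometimes printed transposed). Fitting uses
a QR decomposition without regularization; rank deficiency aborts with the
offending columns named.

The 1550-row training design crosses melanin 1–10 vol.% (10 values), CHbT
0.2–1.0 vol.% (5 values) and 31 saturation pairs. The pair set is
reconstructed from two printed clues: the validation StO2 endpoint 89.1%
equals 0.9 × (100 − 1), identifying StO2 as parameterized by an oxygen
fraction f of the non-met hemoglobin, StO2 = f·(100 − StMet)/100; and
crossing f and StMet over 0–100% in 20% steps yields exactly 31 unique
pairs (the StMet = 100 column collapses to a single point), matching
1550 = 10 × 5 × 31 with no arbitrary padding. The pair grid is serialized
with every fitted model so an alternative reading can be dropped in.

Estimation applies N2 pixel-wise and derives CHbT as the sum of the three
hemoglobin estimates and the saturations by their ratio definitions.
Negative concentration estimates are reported as-is — clipping before
classification would silently bias the features — but pixels with
CHbT ≤ 0 are masked invalid and excluded from saturation computation.

### What recovery is and is not possible

Three observables cannot determine four chromophores pointwise: at any
single operating point the Jacobian of XYZ with respect to
(CHbT, Cm, StO2, StMet) has a one-dimensional null space that mixes the
two saturations. Recovery across a test set therefore rests on the
curvature of the concentration→XYZ manifold, which the quadratic features
capture. The in-silico validation (63 held-out combinations interleaving
the training axes: CHbT {0.3, 0.5, 0.7}, Cm {1.5, 3.5, 5.5}, 7 saturation
pairs at f ∈ {50, 70, 90}% spanning StO2 10–89.1%) reflects this
structure: melanin and total hemoglobin are recovered almost perfectly,
the saturations well, and deoxyhemoglobin — the residual of the
ill-conditioned direction — worst. This ordering is a property of the
physics, not of the sample size: it is unchanged under 4× the photon
budget, different LUT seeds, either bundled illuminant, and perturbations
of the methemoglobin table. The validation report emits RMSE in both
native units and relative percent, since either convention may be wanted.

## Canonical discriminant analysis

Severity classification uses canonical discriminant analysis on
(T, CHbT, StO2, StMet) with their second-order terms, T being time after
injury in seconds (24/48/72 h = 86400/172800/259200 s). "Second-order
terms" is read as squares plus all pairwise cross-products (14
predictors); a squares-only variant (8 predictors) is available since the
phrase is ambiguous. Features are standardized internally (the raw scales
span ten orders of magnitude once T² enters), the pooled within-class
scatter is whitened by symmetric eigendecomposition — switching to a
pseudo-inverse, with a flag on the model, when the scatter is singular —
and the canonical axes are the leading eigenvectors of the whitened
between-class scatter, scaled so the canonical variates z1, z2 have unit
pooled within-class variance. Wilks' Λ = Π 1/(1+λᵢ) summarizes
separation (1 = none); the statistic is reported without a distributional
test. Classification is nearest-centroid in canonical space with exact
ties broken to the lowest class index and flagged.

Evaluation mirrors small-sample practice: leave-one-out cross-validation
refits the model once per held-out sample (an optional `unit` argument
holds out whole subjects instead), and one-vs-rest ROC AUC scores each
class by negative distance to its centroid — the source method does not
state its ROC score, so this choice is documented to keep AUCs comparable
run to run. The AUC uses the exact midrank identity, equivalent to
trapezoidal integration with tied scores midranked.

Pixel-wise severity maps apply the fitted discriminant to every valid
pixel of the hemoglobin maps at a stated time after injury, yielding a
label image, the canonical coordinate planes, and per-class occupancy
rates.

## Synthetic data: what it emulates and what it does not

No imaging data accompany the method, so the package generates its own
study-shaped inputs:

* `run_insilico` reproduces the noise-free validation loop exactly as
  described above — no camera step and no sensor noise, matching the
  stated noise-free design (noise injection exists but is off by
  default).
* `make_phantom` builds region-wise XYZ (or RGB) images from concentration
  sets with ground-truth maps, for end-to-end map tests.
* `make_study` draws per-subject ROI-mean features for the 3-group ×
  5-subject × 3-timepoint design from Gaussian group templates. The
  template means are *synthetic fixtures* — the source prints no ROI-mean
  values — chosen once to follow the reported qualitative trends: controls
  flat (CHbT 0.60 vol.%, StO2 45%, StMet 5%); superficial burns with a
  StMet peak at 24 h (30%) resolving by 72 h and StO2 dipping then
  recovering; deep burns with StO2 depressed at all timepoints (~20–25%),
  CHbT declining and StMet strongly elevated (60% at 24 h). SDs (0.05
  vol.%, 5%, 2–8%) give clear but not degenerate separation.

Passing tests on these generators demonstrate that the pipeline machinery
is correct and that the discriminant attains high accuracy *under the
template's effect sizes*; they do not demonstrate classification accuracy
on real wounds, where spatial heterogeneity, scattering variability,
camera noise and inter-subject variation all degrade performance.
Likewise the phantoms have piecewise-constant optics with no anatomical
texture, vasculature or wound-boundary geometry.

## Problem sizes and runtime

Default problem sizes were chosen so the full pipeline is interactive on a
single core: 31 scattering simulations × 10⁵ photons (~10 s), the
1550-row training build by reweighting (~40 s), the regression fit and the
63-sample validation (< 2 s), and the study/CDA stage (< 5 s). The unit
tests use a 2×10⁴-photon table for pipeline checks and the full 10⁵-photon
configuration for acceptance-level checks.

## Known limitations

* Scattering is fixed at the typical spectrum; per-subject or per-severity
  scattering changes are not estimated, and crosstalk among four
  chromophores estimated from three channels is intrinsic.
* The 5-mm slab under-reports red-region reflectance relative to a
  semi-infinite dermis (config option available).
* The methemoglobin table is a landmark interpolation, not a verbatim
  literature tabulation; the validation statistics were checked to be
  stable under plausible variations of it, but absolute agreement with any
  specific published aquomet curve is not claimed.
* StO2 root-mean-square error in the in-silico validation is ~7 percentage
  points under the default test pairing; it is reported alongside the
  correlations and is sensitive to the (unrecoverable) exact composition
  of the held-out sample set.
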