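# burnchrom

Burn-severity imaging from RGB photographs via hemoglobin chromophore
estimation.

## The problem

Assessing how deep a burn goes is decisive for treatment — superficial
dermal burns heal with supportive care, deep dermal burns need grafting —
yet visual examination is only ~60–75% accurate and the instrumented
alternatives (laser Doppler, OCT, photoacoustics, spatial frequency domain
imaging) are costly or slow. An ordinary RGB camera sees skin through the
absorption of four chromophores: melanin (Cm) in the epidermis and
oxygenated, deoxygenated and methemoglobin (CHbO, CHbR, CmetHb) in the
dermal blood. Thermal injury reorganizes the hemoglobin pool, so the
derived parameters

- total hemoglobin **CHbT = CHbO + CHbR + CmetHb** (vol.%),
- tissue oxygen saturation **StO2 = 100·CHbO/CHbT** (%),
- methemoglobin saturation **StMet = 100·CmetHb/CHbT** (%)

carry burn-depth information pixel by pixel. `burnchrom` is for researchers
in biomedical optics and wound imaging who want this pipeline —
physics-based forward model, empirical inverse, and discriminant
classifier — as tested, scriptable R functions.

## The method

1. **Forward model.** Skin is a two-layer slab (epidermis 0.06 mm with
   melanin, dermis 4.94 mm with blood, both n = 1.4, reduced scattering
   μs′(λ) = 2×10⁵λ⁻¹·⁵ + 2×10¹²λ⁻⁴). One zero-absorption ("white") Monte
   Carlo run per wavelength records each detected photon's per-layer path
   lengths (lₑ, l_d); the diffuse reflectance for any absorption
   combination follows by Beer–Lambert reweighting:
   Θ(λ) = N⁻¹ Σᵢ wᵢ exp(−μₐ,ₑ lₑ,ᵢ − μₐ,d l_d,ᵢ).
2. **Colorimetry.** Spectra integrate to CIEXYZ at 10-nm steps over
   400–700 nm, X = kΣE x̄ Θ etc., with k = 100/ΣE ȳ so the perfect
   diffuser has Y = 100. A 3×3 matrix N1 fitted on a 24-chip color chart
   maps camera RGB to XYZ; a white-diffuser reference image corrects
   illumination non-uniformity.
3. **Inverse.** 1550 forward-simulated (concentration, XYZ) pairs — 10
   melanin × 5 CHbT × 31 saturation pairs — train four least-squares
   regressions of the concentrations on the quadratic features
   (1, X, Y, Z, X², Y², Z², XY, XZ, YZ), packed as the 4×10 matrix **N2**.
   Applied pixel-wise, N2 turns an XYZ image into chromophore and
   hemoglobin-parameter maps.
4. **Classification.** Canonical discriminant analysis on
   (T, CHbT, StO2, StMet) and their second-order terms separates control /
   superficial / deep burn classes; pixels are labeled by nearest group
   centroid on the canonical plane (z1, z2), with leave-one-out
   cross-validation and one-vs-rest ROC AUC for evaluation, and Wilks' Λ
   summarizing separation.

## Worked example

```r
library(burnchrom)

# 1. scattering path-length tables: 31 wavelengths x 1e5 photons (~10 s)
lut <- simulate_scattering(n_photons = 1e5, seed = 1)

# 2. forward-simulate the 1550-row training set and fit the inverse (~40 s)
training <- build_training_set(lut, expected_size = 1550)
n2 <- fit_n2(training)
n2
#> n2_fit: 4x10 quadratic XYZ->concentration map (1550 training rows, illuminant D65)
#>   training R^2: c_hbo=0.8267, c_hbr=0.4378, c_methb=0.7443, c_m=0.9860

# 3. in-silico validation on 63 held-out concentration combinations
run_insilico(lut, n2)
#> insilico_report: 63 samples (LUT: 100000 photons, seed 1)
#>   param     pearson_r       rmse_abs     rmse_rel_%
#>   c_hbo        0.9772        0.03799          23.72
#>   c_hbr        0.6335        0.07045          102.3
#>   c_methb      0.9433        0.05134          681.9
#>   c_m          0.9978         0.2496          12.73
#>   c_hbt        0.9856        0.02833           6.27
#>   sto2         0.9690          6.955          22.23
#>   stmet        0.9448          9.306          654.1

# 4. discriminate burn severity on a synthetic 3-group x 5-subject study
study <- make_study(seed = 1)
des <- study_design(study)
fit_cda(des$features, des$labels)
#> cda_fit: 3 classes (burn70, burn78, control), 45 samples, 14 features, 2 axes
#>   Wilks' lambda = 0.002176; eigenvalues: 55.81, 7.091
cv <- loocv(des$features, des$labels)
cv$rates
#>  burn70  burn78 control
#>     100     100     100
roc_auc(cv$scores, des$labels)
#>  burn70  burn78 control
#>   1.000   0.996   1.000
```

Reading the numbers: the training R² values show what a quadratic in three
tristimulus values can and cannot capture — melanin almost fully, the
individual hemoglobin derivatives only partially, because four chromophores
are being estimated from three channels. On held-out samples the
correlations tell the same story from the other side: Cm (r = 0.998), CHbT
(0.986) and StO2 (0.969) are recovered well, CmetHb and StMet well
(≈ 0.94), and CHbR — the residual of the ill-conditioned direction — worst
(0.63). The discriminant stage then separates the three severity groups
essentially perfectly under the synthetic study's effect sizes (per-class
LOOCV 100%, AUC ≥ 0.996).

Pixel-wise maps work the same way on images: `estimate_concentrations()`
turns an XYZ image into `hemo_maps`, and `severity_map()` labels each pixel
by the fitted discriminant. A command-line wrapper is installed at
`inst/cli/burnchrom` (`simulate-lut`, `fit-inverse`, `calibrate`,
`estimate`, `fit-cda`, `classify-image`, `validate-insilico`,
`make-phantom`, `make-study`, `pipeline`), each taking `--config`, `--out`,
`--seed`, `--log-level`.

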