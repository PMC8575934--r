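---
title: "chiromet: models, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chiromet: models, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiromet)
```

## The sensing model

Chirality sensing with an achiral chromophoric probe rests on two linear
responses. After derivatization, each analyte adduct contributes to the UV
absorbance in proportion to its **total** concentration, because both
enantiomers of an analyte share the same molar absorptivity; and it
contributes to the circular dichroism in proportion to the **difference**
of its enantiomer concentrations, because the two enantiomeric adducts
have exactly mirror-image CD. For analytes $i$ with per-enantiomer
concentrations $c_{i,R}, c_{i,S}$ (mM):

$$A(\lambda) = \sum_i (c_{i,R} + c_{i,S})\,\varepsilon_i(\lambda), \qquad
\theta(\lambda) = \sum_i (c_{i,R} - c_{i,S})\,\Delta\varepsilon_i(\lambda).$$

We work on the instrument scale throughout: CD in millidegrees, UV in
absorbance units, concentrations in mM, wavelengths on a canonical
250–450 nm grid at 1 nm (201 points). Whether CD is processed in mdeg or
converted to $\Delta\varepsilon$ is immaterial for every linear pipeline
in the package (it is a per-spectrum rescaling), so no conversion layer
exists.

Two solvents (DCE and MeOH) give distinct basis spectra for most adducts
— conformational equilibria and intramolecular hydrogen bonding shift the
bands — which is what makes four-block (CD/UV × solvent) data fusion
informative. The model assumes strict additivity: no analyte–analyte or
probe–probe spectral interaction, mirroring the interference-free
behaviour of the sensing chemistry this emulates. Interference modelling
is deliberately out of scope.

## The synthetic world

`make_preset_basis()` encodes each analyte's per-solvent UV and CD basis
as a sum of Gaussian bands
$v(\lambda) = a\,\exp(-4\ln 2\,(\lambda-\mu)^2/w^2)$ ($w$ = FWHM). The
band constants are presets chosen once to satisfy the qualitative facts
known for the coumarin-probe adducts, and the test suite asserts them:

* PMP's CD crosses zero at 340 nm (two opposite bands placed
  symmetrically about 340 nm, so the crossing is exact) and is nearly
  solvent-invariant (cosine similarity > 0.95 across solvents);
* PEA's CD is silent at 400 nm (all bands centred ≤ 340 nm; the residual
  at 400 nm is < 1% of its maximum) but strong at 340 nm — together with
  PMP's crossing this creates the complementary-wavelength univariate
  mode;
* PEA and PPA change CD shape strongly with solvent (cosine < 0.8);
* UV bases are distinct between analytes (the probe is useful precisely
  because each adduct shows a characteristic UV change; an early draft
  with near-collinear UV bases made totals ill-determined and was
  corrected), with one deliberate exception: PEA and PPA have nearly the
  same UV in MeOH (cosine > 0.95) but split widely in DCE — the solvent
  effect that motivates measuring in two solvents;
* CD band mass lies in roughly 270–320 and 360–430 nm, UV mass in
  270–330 and 400–450 nm.

Amplitudes are responses per mM (CD ≈ 2–3 mdeg/mM, UV ≈ 0.1–0.3 AU/mM),
giving signals of tens of mdeg at the 0–13 mM design range.

**Noise.** Each simulated point $y$ becomes
$y\,(1+\mathcal N(0,\sigma_m)) + \mathcal N(0, f_a \cdot
\max|\text{signal}|)$ with defaults $\sigma_m = 0.01$ and $f_a = 0.003$,
the additive floor referenced to the per-modality maximum over the whole
noiseless dataset. This mimics a fixed instrument noise floor plus
proportional error. Noise streams are keyed by (master seed, sample id)
through a stable string hash, so extending a design never reshuffles the
noise of existing samples.

**Designs.** The quaternary design (PEA + PMP, CD and UV in DCE, 4
response channels) draws every enantiomer concentration uniformly on
(0, 13) mM; the octonary design (all four analytes, four blocks, 8
channels) uses (0, 5) mM. The original experiments used hand-designed
training compositions that are not machine-readable here; uniform random
compositions stand in for them. This matters for interpreting results:
designed calibration sets are better conditioned than random ones, so
campaign error statistics from this generator are comparable to, but not
a reproduction of, the measured campaigns.

**What a green test establishes.** The generator shares the estimator's
own linearity assumption, so end-to-end recoveries mainly certify the
algebra (decomposition, regression, scaling bookkeeping, leak-free CV) —
not robustness to baseline drift, wavelength miscalibration, band-shape
nonlinearity or kinetic effects, none of which are modelled.

## Estimators and numerical choices

* **PCA** is computed by SVD of the centred matrix — deterministic and
  numerically stable; NIPALS is reserved for the latent-variable methods.
  Each component's sign is fixed so its largest-|loading| entry is
  positive, making serialized models comparable. (Textbook treatments
  occasionally swap which factor of $A = U\Sigma V^\top$ collects the
  eigenvectors of $A^\top A$ versus $AA^\top$; the standard convention is
  used.)
* **PCR** truncates the requested component count at the numerical rank
  (singular values above $10^{-9}\sigma_1$), so LOOCV can sweep $k$ past
  the rank of noiseless data instead of failing in OLS; the OLS step
  itself refuses rank-deficient score matrices rather than silently
  pseudo-inverting.
* **PLS2** is NIPALS with the inner loop iterated as the algebraically
  identical power step $w \leftarrow CC^\top w$, $C = E^\top F$
  (cheaper per iteration, same fixed point). Convergence is
  $\lVert w - w_\text{old}\rVert < 10^{-10}$ with a cap of 10⁴
  iterations. A cap of 500 proved too small on ordinary noisy data: when
  the top two covariance eigenvalues are close (ratios ≈ 0.96 occur
  routinely in LOOCV folds) power iteration legitimately needs more than
  500 steps at this tolerance. Exceeding the cap, or a response with zero
  covariance to X at the first latent variable, raises an error naming
  the latent variable. Latent-variable extraction stops early once the X
  or Y residual is numerically exhausted; predictions with larger
  requested $k$ clamp to the extracted count, which keeps training $R^2$
  monotone and noiseless LOOCV curves flat beyond the true rank.
* **MBPCA / MBPLS** use the consensus formulation with super-score
  deflation: per component/LV every block gets weights, scores and
  loadings, plus a super score combining the block scores. The MBPLS
  super weights are $\omega_b = \lVert w_b\rVert$ (block slice of the
  jointly normalized weight), so the super score equals the concatenated
  score and predictions coincide exactly with PLS2 on the concatenated
  matrix — the correctness oracle asserted by the tests (the two code
  paths are written independently). **Block importance** is
  $\omega_{b}^2 / \sum_{b'} \omega_{b'}^2$ per LV, the standard
  squared-weight-norm definition; the original analysis names the
  quantity without printing a formula, and this definition reproduces its
  qualitative statements. Rows sum to one by construction.
* **LASSO** is cyclic coordinate descent on
  $\tfrac1{2n}\lVert y - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1$,
  intercept handled by centring and never penalized, convergence when the
  largest coefficient change in a sweep is below $10^{-8}$, cap 10⁴
  sweeps. On a fine wavelength grid adjacent autoscaled columns are
  near-duplicates and the solution is barely unique; coordinate descent
  then converges very slowly and can hit the cap at small $\lambda$. The
  error is raised honestly; practical use (and the test suite) either
  coarsens the grid or keeps $\lambda \gtrsim 0.05\,\lambda_\max$. When
  no penalty is supplied, the LASSO-assisted pipelines choose $\lambda$
  by LOOCV over a 20-point log grid $10^{[-4,1]}\lambda_\max$.
* **LOOCV** refits all preprocessing inside every fold — scaling
  parameters never see the held-out sample. `selected_k` is the argmin of
  the RMSE curve with a smallest-$k$ tie rule at relative tolerance
  $10^{-6}$. Duplicated rows make LOOCV optimistic (the left-out row's
  twin remains in training); this is flagged in the result, not raised.
  "Averaged $R^2$" means the mean of per-channel $R^2$, with
  zero-variance channels excluded under a warning.
* **Preprocessing** records (column means, column divisors, block
  divisors) are estimated on training rows and applied frozen elsewhere;
  every transform inverts through its record to better than $10^{-10}$
  relative. Zero-variance columns pass through with divisor 1 (and a
  warning) to keep wavelength indexing stable — LASSO is the sanctioned
  way to drop uninformative variables. Block scaling divides each
  autoscaled block by $\sqrt{p_b}$ (hard) or $p_b^{1/4}$ (soft), the
  conventional multiblock definitions, adopted because the original
  formulas are not available in the main text.

## Chemistry-facing outputs

`derive_chirality()` reports total (mM), er as a major:minor pair printed
to one decimal and summing to 100.0, ee, and the major configuration.
Negative predicted concentrations are reported raw by default — clipping
at zero biases low-concentration channels — with `clip = TRUE` available.
|ee| below 0.01 is labelled a racemate. Absolute configuration follows
the generator's sign convention directly; a real-data deployment would
determine it against a reference sample of known configuration, a
mechanism this package does not need.

The univariate mode inverts a least-squares line through (signed
enantiomer difference, CD at the readout wavelength) and requires the
total concentration to be known — its stated limitation, and the reason
the multivariate pipelines exist. Readings implying |ee| > 1 are clipped
to ±1 with a warning.

## Known limitations

* The block-importance *ordering* across latent variables depends on the
  variance structure of the compositions. With uniform random designs
  the total-concentration (UV-driven) directions carry as much response
  variance as the enantiomer-difference directions, and the first LV is
  usually UV-heavy; the CD blocks dominate the LV that carries the er
  information (asserted in the tests), which need not be LV1 as it was
  in the measured campaigns.
* Campaign error statistics are bounded by, not equal to, the measured
  ones: random training designs, Gaussian band shapes and the two-term
  noise model are idealizations.
* The JCAMP-DX reader covers only the fixed-abscissa AFFN
  `(X++(Y..Y))` form; compressed encodings are rejected.
* Derivative spectra, smoothing and scatter correction are not
  implemented — the emulated assay does not use them.
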