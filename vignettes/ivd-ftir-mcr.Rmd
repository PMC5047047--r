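---
title: "Resolving intervertebral disc matrix components from FTIR images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving intervertebral disc matrix components from FTIR images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivdmcr)
```

## The problem and the model

A hyperspectral FTIR image of a paraffin-embedded intervertebral disc (IVD)
section is a cube of absorbance spectra, one per pixel. Under the
Beer–Lambert law each pixel spectrum is a non-negative linear mixture of the
spectra of the chemical species present — collagen type I, collagen type II,
proteoglycan (PG) populations, elastin, and the embedding paraffin — so the
pixels-by-wavenumbers matrix `D` is bilinear:

\[ D \approx C\,S^{\top}, \qquad C \ge 0, \]

with `C` the per-pixel concentrations (one column per component) and `S` the
component spectra. Multivariate curve resolution by alternating least
squares (MCR-ALS) estimates both factors from the data alone; no reference
spectra enter the fit. Reference band models are used only afterwards, to
*label* the recovered factors.

The pipeline follows the standard transflectance workflow:

1. **Second-derivative preprocessing** (`second_derivative()`): a
   Savitzky–Golay filter, polynomial order 3, 15-point window (28 cm⁻¹ at
   the default 2 cm⁻¹ channel spacing of 4 cm⁻¹-resolution data). The
   second derivative sharpens overlapped bands and annihilates additive
   baselines up to the linear term exactly (a quadratic baseline survives
   only as a per-pixel constant of size `2a` in per-channel² units). The
   output is left in per-(channel step)² units; only relative values matter
   downstream. Edge channels are computed from the polynomial fitted to the
   one-sided end window so the axis length never changes.
2. **Masking** (`compute_mask()`): a pixel is retained iff its
   2nd-derivative value at the channel nearest 1554 cm⁻¹ — the protein
   amide II trough — is strictly below 0. Tissue has a deep negative amide
   II lobe; paraffin- or substrate-only pixels do not. With noise, roughly
   half of the non-tissue pixels leak through the threshold; this is
   harmless because paraffin is carried as an explicit factor of the model,
   exactly as the embedding medium is treated as an additional signal
   contribution rather than being corrected away.
3. **Unmixing** (`resolve()`): region selection (950–1300 cm⁻¹ by default;
   950–1600 cm⁻¹ is the other standard choice), assembly of the masked
   pixel matrix, factor initialisation, and constrained ALS. The matrix
   fed to ALS is the *negated* second derivative, so absorbance bands
   appear as positive peaks and non-negativity of `C` is meaningful; the
   profiles `S` keep their genuine negative side lobes and are not
   sign-constrained.
4. **Mapping** (`tissue_map()`, `ratio_map()`, `assign_factors()`,
   `cos_peak_position()`): amide III (1186–1297 cm⁻¹) peak-integration maps
   as the per-pixel "tissue" normaliser, component/tissue ratio maps,
   correlation-based factor labelling against a reference library, and the
   C–O–S peak position (1100–1140 cm⁻¹ window) that discriminates the two
   PG populations.
5. **Regional gradients** (`width_normalized_profile()`,
   `integrate_region()`): a 10-row area of interest across the middle of
   the section is averaged column-wise, the tissue width is rescaled to
   0–100 % (101 points, 1 % spacing), and areas under the curve over
   aAF = 10–20 %, NP = 51–61 % and pAF = 85–95 % windows become the
   per-sample semi-quantitative parameters. (An 85–100 % posterior window
   variant is available via `regional_windows(paf_to_100 = TRUE)` because
   the two conventions coexist in practice.)
6. **Association** (`nonparametric_regression()`, `correlate_cohort()`):
   Theil–Sen slope and intercept with significance from the two-sided
   Kendall rank test — the standard reading of "non-parametric linear
   regression". The exact permutation null is used for n ≤ 10 without
   ties; otherwise a normal approximation with continuity correction and
   the tie-corrected (tau-b) variance. At n = 10 the approximation agrees
   with the exact null to about 0.01 in p. The ordinal histological grade
   (0–6) enters as a rank, which is valid for both statistics. No
   multiplicity adjustment is applied by default (per-test α = 0.05);
   Benjamini–Hochberg is available via `p_adjust = "BH"`.
7. **T2\* relaxometry** (`t2star_fit()`): ordinary least squares of
   `log(I)` on echo time over the five-echo train
   (5.7, 10.9, 16.05, 21.2, 26.4 ms); `T2* = -1/slope`. Exact on noiseless
   mono-exponential decays.

## Constraints and the ALS engine

`als_optimize()` alternates exact least-squares half-steps for `C` and `S`.
With the default `mcr_constraints(alpha = 1)` the concentration half-step is
solved as an exact non-negative least-squares problem via fast combinatorial
NNLS (rows grouped by active set). Because each half-step is an exact
minimiser over a feasible set containing the previous iterate, the lack of
fit

\[ \mathrm{LOF} = 100\sqrt{\sum (D - CS^{\top})^2 / \sum D^2} \]

is non-increasing by construction. For `0 < alpha < 1` the softer blend
`X ← (1−α)X + α max(X, 0)` is applied instead; it is not a descent step, so
monotonicity is maintained by backtracking on `α` within the iteration
(α → 0 recovers plain ALS, which cannot increase the residual). We found the
soft blend too weak to pin the rotational ambiguity of realistic disc
mixtures — factorizations of equal fit but mixed factors abound — which is
why the hard step is the default. Iterations stop when the relative LOF
change drops below `tol = 1e-6` or at `max_iter = 500`. Profiles are kept
unit-norm with their largest-magnitude lobe positive; all magnitude lives in
`C`. Degenerate normal equations fall back to a trace-scaled ridge
(λ = 1e-10 of the mean diagonal) with a warning.

Exact NNLS has one systematic side effect: where a component is truly
absent, clipping noise at zero biases its concentration upward, and over
many iterations the profile half-step compensates with spurious negative
dips in the weakest profiles. The `resolve()` polish therefore ends with
*sparse refits*: concentrations below 2 % of their column maximum are set to
exactly zero and all profiles are re-derived in one least-squares solve.

## Finding the right factorization: the local-rank strategy

Raw abstract factors (NIPALS or SVD) are poor starting points for hard
constrained ALS on these images: the iteration locks into a mixed
factorization within a few steps. `resolve()` therefore defaults to a staged
strategy built only from the data's own spectral selectivity:

1. **Paraffin anchor.** The average spectrum of the *masked-out* pixels is
   a data-driven paraffin estimate (those pixels contain only embedding
   medium or substrate). Its concentration map is read off the
   1440–1490 cm⁻¹ CH₂/CH₃ deformation window, where tissue components are
   silent.
2. **Collagens from amide II.** A two-factor sub-MCR of the
   1520–1600 cm⁻¹ window separates the two collagens (amide II centres
   1558 vs 1552 cm⁻¹). Polysaccharides have no amide II, so both annulus
   margins (collagen I) and nucleus pixels (collagen II) are near-pure
   there and the two-component problem is easy.
3. **PG populations from the deflated residual.** With paraffin and the
   collagen maps fixed, the residual of the analysis region contains the
   PG factors, whose pure zones (nucleus core for the native pool,
   posterior transition zone for the altered pool) surface after
   deflation.
4. **Assembly and polish.** The assembled profiles seed a short hard ALS
   over the full region, followed by sparse refits. Finally the
   outer-annulus collagen profile is re-read from its *margin key set* —
   the 300 strongest low-PG pixels (ranked by collagen share, restricted
   to pixels below the median C–O–S-window energy) — subtracting only the
   factors genuinely present there (the other collagen and paraffin).
   This breaks a subtle error loop in which NNLS clipping bias in the PG
   maps leaks into the collagen profile and back.

The `init_method` argument (`"nipals"` or `"svd"`) selects the eigenanalysis
backend used by the abstract-factor stages; the two give numerically
equivalent subspaces, which the test suite verifies on 50 seeded matrices.
`strategy = "abstract"` bypasses the staged path and feeds the abstract
factors to ALS directly; it is also the automatic fallback whenever the
image axis does not span the anchor windows, the mask excludes no pixels, or
`k` is outside 3–6.

Factor labels come from `assign_factors()`: Pearson correlation between each
profile and the negated second derivative of each library entry, with the
exact optimum of the injective assignment (enumeration over at most 8!
candidate matchings — identical to the Hungarian optimum, deterministic, ties
broken by factor index). Unmatched factors are labelled `"extra"`. Because
the printed PG shift (1126 → 1124 cm⁻¹) equals the channel spacing,
`cos_peak_position()` refines the argmax by three-point parabolic
interpolation and reports to 0.1 cm⁻¹.

## What the phantom emulates — and what it does not

`generate_phantom()` builds a synthetic sagittal IVD section with full
ground truth. Its defaults are the package's study conditions:

* **Geometry**: 60 × 208 pixels, 900–1800 cm⁻¹ at 2 cm⁻¹ spacing; a
  non-tissue frame of 4 rows / 8 columns, of which the outermost 2 columns
  per side are substrate-only (bare baseline) and the rest paraffin-only —
  both masking failure modes.
* **Spatial chemistry** (anterior → posterior fraction *t*): collagen I
  `(2t−1)⁴`, maximal at both annulus margins and absent in the nucleus
  core; collagen II a broad half-ellipse plateau over nucleus and inner
  annulus; the native PG pool a narrow nucleus-core Gaussian
  (centre 0.50, σ 0.12) at twice the collagen II amplitude — the healthy
  nucleus is proteoglycan-dominated; the altered PG pool a posterior
  Gaussian (centre 0.70, σ 0.12), placed in the posterior nucleus /
  inner posterior annulus where altered PG accumulates in degenerate human
  discs. Components vanish outside their zones; this reflects
  immunohistochemistry and is also what makes the non-negative
  factorization identifiable.
* **Texture**: every component is modulated by an independent smooth random
  field (±30 %; a low-order 2-D cosine expansion) emulating lamellae, cell
  clusters and infiltration heterogeneity. Paraffin's field spans
  near-zero to full (0.10–1.30) because dense matrix excludes wax; without
  pixels of near-zero paraffin, a one-parameter family of factorizations
  trading paraffin against tissue components is feasible — the
  "paraffin contribution in collagen profiles" ambiguity seen in practice.
* **Degeneration** `d ∈ [0, 1]` scales the native pool by `1 − 0.8d` and
  the altered pool by `0.2 + 0.8d`; the altered pool's C–O–S band is
  planted at `1126 − pg_shift` (default 1124 cm⁻¹). The default `d = 0.5`
  represents the mildly degenerate state an enzymatic injection model
  induces. At the extremes one pool is nearly unexpressed and cannot be
  unmixed from a single section; the control/degenerate *pair* is then
  collated into one matrix before resolution, which is also how paired
  sections are analysed in practice.
* **Distortions**: per-pixel random polynomial baselines (order 2,
  coefficient scale 0.05) and white Gaussian noise of σ = 0.005 absorbance
  (≈ 0.3 % of the maximum signal, realistic for 256-fold aggregated
  focal-plane-array data). Noise propagation sets a hard ceiling here: at
  σ = 0.01 the weakest component's map recovery caps near 0.95 correlation
  *even when the true profiles are supplied*, so the default sits where
  the method's performance, not the noise floor, is measured. Per-pixel
  multiplicative gain is available through `add_distortions()` but is not
  part of the default mixing model, which is strictly
  `C*S*ᵀ + baseline + noise`.
* **Reference spectra** are Gaussian band models at literature positions
  (collagen amide II 1558/1552, amide III 1240/1238 with the 1202
  component, collagen II C–O 1082, PG bands 1030/1064/1126 (or 1124)/1160/
  1228/1376, elastin 1516/1160, paraffin 1473/1464/1378 plus weak
  crystalline-alkane progression bands at 1303 and 1168). Amplitudes are
  synthetic choices — no measured spectra are distributed — and are the
  least validated part of the generator.
* **Covariates**: glycosaminoglycan and hydroxyproline as affine functions
  of the true nucleus abundances plus Gaussian noise at a cohort
  signal-to-noise ratio of 3; T2\* produced by actually fitting a noisy
  synthetic echo train; the ordinal grade (0–6) by quantile-binning
  inverse native-PG abundance.

What passing tests on this phantom do **not** show: robustness to Mie
scattering, standing-wave distortions or dispersive line shapes (none are
simulated — deliberately, since no spectral correction is applied in the
workflow the package implements); performance when component spectra differ
from the library more than band-position noise; behaviour on sections whose
geometry deviates strongly from the single-disc layout the width
normalisation assumes.

## Numerical choices and degenerate inputs

* Wavenumber axes are stored descending (acquisition order) and all range
  operations are order-agnostic; region bounds are inclusive.
* The tissue map integrates the *rectified* negated second derivative
  (`max(−d2, 0)`): the unrectified integral of a derivative across a fully
  contained band is zero, so rectification is what makes peak integration
  of derivative spectra meaningful.
* Ratio maps guard the division with ε = 10⁻³ × the median tissue value
  over the mask; pixels below ε are missing, not infinite.
* The IVD width is detected as the first/last AoI column with ≥ 3 tissue
  pixels; a tissue extent under 3 columns is a degenerate-section error.
  Profile resampling uses linear interpolation onto the fixed 0–100 % grid;
  regional integrals interpolate non-integer window edges so adjacent
  windows add exactly.
* Empty masks, all-zero data matrices, non-decaying echo trains, constant
  covariates and cardinality mismatches raise typed errors
  (`empty-mask`, `degenerate-input`, `no-decay`, `degenerate-data`,
  `incompatible-*`) rather than propagating NaNs.

## A worked run

```{r, eval = FALSE}
ph   <- generate_phantom(phantom_config())
d2   <- second_derivative(ph$image)
mask <- compute_mask(d2)
model  <- resolve(d2, mask, k = 5, region = c(950, 1300))
labels <- assign_factors(model, default_library())
tissue <- tissue_map(d2, mask)
pg1    <- ratio_map(component_map(model,
                    labels$factor[labels$component == "PG1"]), tissue)
aoi  <- centered_aoi(tissue)
prof <- width_normalized_profile(extract_aoi(pg1, aoi),
                                 extract_aoi(tissue, aoi),
                                 component = "PG1", sample_id = "demo")
integrate_region(prof, 51, 61, region = "NP")
```

`run_pipeline(analysis_config())` chains the same stages over a simulated
cohort and returns a manifest with the regional-parameter table, covariates
and (for cohorts of at least five samples) the association results.

## Problem sizes used by the tests

The unit suite exercises the full-size 60 × 208 default phantom for the
recovery and PG-signature checks, a 36 × 120 grid for the end-to-end
pipeline demos, 50 seeded matrices up to 20 × 20 for the NIPALS/SVD
equivalence, the complete 8! permutation set for the rank-test calibration,
and 200 seeded 40-sample cohorts for the power check. These sizes were
chosen so each property is measured where it is informative while the whole
suite stays quick to run.

## Known limitations

* The staged resolution strategy is specific to the five-component disc
  problem (3–6 factors, axis spanning 950–1600 cm⁻¹); other systems fall
  back to plain abstract-factor ALS, which inherits the usual MCR
  rotational-ambiguity caveats.
* Factor labelling is correlation-based against an idealised band-model
  library; heavily distorted measured profiles may assign poorly even when
  the maps are right.
* The soft-constraint surrogate for proprietary constraint schemes is a
  transparent blend, not a reconstruction of any particular commercial
  implementation.
* Per-sample inference treats samples as independent; repeated discs from
  one animal are not modelled hierarchically.
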