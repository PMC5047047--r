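# ivdmcr

Multivariate curve resolution of hyperspectral FTIR images of
intervertebral disc (IVD) tissue.

FTIR imaging of a single paraffin-embedded disc section records an
absorbance spectrum at every pixel. Because absorbances add
(Beer–Lambert), the pixels-by-wavenumbers matrix is bilinear,
`D ≈ C Sᵀ` with non-negative concentrations `C` and component spectra `S`.
`ivdmcr` implements the full analysis chain that turns such a cube into
biologically labelled maps and per-sample degeneration parameters — the
kind of information that otherwise needs a panel of histological and
immunohistochemical stains on serial sections:

* Savitzky–Golay 2nd-derivative preprocessing (order 3, 15-point window)
  and amide-II spectral masking of paraffin/substrate pixels
  (`second_derivative()`, `compute_mask()`);
* self-contained MCR-ALS with NIPALS or SVD initial estimates, exact
  non-negative least-squares half-steps, and a staged "local-rank"
  initialisation for disc images (`nipals_decompose()`, `als_optimize()`,
  `resolve()`);
* amide-III tissue maps, component/tissue ratio maps, reference-library
  factor assignment, and C–O–S peak positions that discriminate the native
  (≈1126 cm⁻¹) from the altered (≈1124 cm⁻¹) proteoglycan population
  (`tissue_map()`, `ratio_map()`, `assign_factors()`,
  `cos_peak_position()`);
* width-normalized abundance gradients and regional parameters over the
  anterior annulus (10–20 %), nucleus (51–61 %) and posterior annulus
  (85–95 %) windows (`width_normalized_profile()`, `integrate_region()`);
* non-parametric association of regional parameters with histological
  grade, glycosaminoglycan, total collagen and MRI T2\* covariates via
  Theil–Sen regression and the Kendall rank test, plus the log-linear
  T2\* fit itself (`nonparametric_regression()`, `correlate_cohort()`,
  `t2star_fit()`);
* a synthetic disc phantom generator with complete ground truth
  (`generate_phantom()`, `simulate_cohort()`) and an end-to-end pipeline
  driver (`run_pipeline()`).

For a full account of the model, the constraints, the phantom's design and
the numerical choices, see the methods vignette
(`vignettes/ivd-ftir-mcr.Rmd`).

## Worked example

```r
library(ivdmcr)

ph   <- generate_phantom(phantom_config())       # 60 x 208 disc section
d2   <- second_derivative(ph$image)
mask <- compute_mask(d2)                         # amide II at 1554, cut at 0
model <- resolve(d2, mask, k = 5, region = c(950, 1300))
model
#> <mcr_model> k = 5, 11244 pixels x 176 channels, LOF 1.693% after 25 iterations (max_iter)

assign_factors(model, default_library())
#>   factor   component     score
#> 1      1  collagen_I 0.9969211
#> 2      2 collagen_II 0.9856762
#> 3      3         PG1 0.9993145
#> 4      4         PG2 0.9991415
#> 5      5    paraffin 0.9993015
```

The five factors recover the planted matrix components; the `score` column
is the Pearson correlation between each resolved profile and the
2nd-derivative reference spectrum of the component it was assigned to. From
here, `tissue_map()` + `ratio_map()` give relative distribution maps,
`width_normalized_profile()` + `integrate_region()` the regional
parameters, and on a control/degenerate pair the nucleus PG1 parameter
drops while PG2 rises with degeneration, with the two resolved C–O–S peaks
about 2 cm⁻¹ apart (≈1126 vs ≈1124 cm⁻¹).

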