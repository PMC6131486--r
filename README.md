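# dscml

Quantitative perfusion imaging from dynamic susceptibility contrast (DSC)
MR, in two complementary ways:

1. **Classical maps.** Convert a 4D signal-intensity series to
   concentration-time curves (`CTC(t) = log(I(t0)/I(t)) / TE`), recover each
   voxel's residue function by block-circulant (delay-insensitive) SVD
   deconvolution of `CTC = A · (CBF·R)` — truncated-threshold cSVD or
   adaptive oscillation-index oSVD — and read off the five standard maps:
   rCBF (peak of `CBF·R`), rCBV (`∫CTC/∫AIF`), MTT (`CBV/CBF`), TTP and
   Tmax (peak times of the tissue curve and residue).
2. **Learned maps.** Train regression models (linear, ridge, kernel ridge,
   ε-SVR, a 7-layer MLP, a 100-tree random forest) that map a voxel's
   concentration curves — optionally with its in-plane patch — plus the
   arterial input function straight to the reference map value, skipping the
   noise-sensitive deconvolution at inference time.

The package also ships the scaffolding such a study needs: a forward
simulator with known per-voxel ground truth (gamma-variate arterial bolus
convolved with delayed exponential residues), a 12-level CBF noise phantom
with additive white Gaussian noise, NRMSE / coefficient-of-repeatability /
Bland–Altman metrics, case-level train/test splitting, and sweep drivers for
training-set size, patch size and noise robustness.

Intended users: researchers in perfusion-weighted imaging and medical image
analysis who need a reproducible, scriptable reference implementation of
SVD-based DSC quantification and of the learned-regression alternative.

## Worked example

```r
library(dscml)

# a synthetic case with known ground truth
sim  <- simulate_case(simulation_config(dim_xyz = c(16, 16, 2), seed = 7))
ctc  <- signal_to_ctc(sim$series)               # exact inverse of synthesis
maps <- maps_from_case(ctc, sim$aif, deconv_config(method = "osvd"))

rel_err <- abs(maps$maps$cbf - sim$truth$maps$cbf) / sim$truth$maps$cbf
summary(as.numeric(rel_err))
#>      Min.   1st Qu.    Median      Mean   3rd Qu.      Max.
#> 4.270e-16 7.667e-14 2.740e-13 4.456e-13 7.706e-13 1.422e-12

# learned reproduction of the oSVD Tmax map from raw curves (5x5 patches)
cases <- lapply(1:6, function(i) {
  s <- simulate_case(simulation_config(dim_xyz = c(20, 20, 2),
                                       delay_range = c(0, 4.5), seed = i))
  cc <- signal_to_ctc(s$series)
  list(ctc = cc, aif = s$aif,
       maps = maps_from_case(cc, s$aif, deconv_config()), id = s$id)
})
sp <- split_cases(1:6, 0.8, seed = 1)           # case-level 4/5 split
tr <- build_dataset(cases[sp$train], "tmax", e = 2, n_samples = 2000, seed = 1)
te <- build_dataset(cases[sp$test],  "tmax", e = 2, n_samples = 500,  seed = 2)

for (fam in c("linear", "random_forest")) {
  m <- fit_regressor(fam, tr$X, tr$y, seed = 1)
  cat(fam, "NRMSE:", round(nrmse(te$y, predict(m, te$X)), 3), "\n")
}
#> linear NRMSE: 0.162
#> random_forest NRMSE: 0.1
```

The NRMSE values are the held-out root-mean-square error of the predicted
Tmax map divided by the range of the reference Tmax values; the nonlinear
forest tracks the deconvolution reference more closely than the linear
baseline, and both errors shrink further at the full experiment scale
(15,000 training voxels from 16 cases).

A thin CLI wraps the same functions for shell use (see `inst/cli/dscml`):

```sh
Rscript inst/cli/dscml simulate --seed 1 --out case/
Rscript inst/cli/dscml compute-maps --ctc case/ctc.nii.gz \
    --aif case/aif.txt --method osvd --out case/maps/
Rscript inst/cli/dscml run --seed 1 --out run/
```

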