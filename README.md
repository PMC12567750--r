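# fnirscal

Monte Carlo depth-sensitivity calibration for fNIRS probes.

## The problem

Functional near-infrared spectroscopy (fNIRS) senses cortical hemodynamics
through the scalp; how deep a channel "sees" is governed by the
source-detector separation (SDS). Probes are usually built with one fixed
separation for every subject and every cortical target, although the
scalp-to-cortex distance varies substantially across regions and
individuals. `fnirscal` is for researchers designing or calibrating fNIRS
probes: it simulates near-infrared photon transport through layered head
phantoms, quantifies the **sensitivity at depth** (SAD) of each probe
geometry, fits a Gaussian-process surrogate of SAD over separation and
depth, and inverts it to recommend the separation needed to reach a target
cortical depth at a requested sensitivity level.

## The model

* **Phantoms.** Planar slab stacks (scalp-muscle, cranium, CSF, brain) on a
  64 x 64 x 64 mm voxel tally grid, with *continuous* layer boundaries so
  sub-voxel CSF layers survive. Layer thicknesses for eight adult cadaveric
  heads (measured from MRI) and tissue optical properties at 735 nm
  (mu_a, mu_s, Henyey-Greenstein g, refractive index n per layer) ship with
  the package.
* **Transport.** Weighted photon packets from a 70-degree cone source:
  exponential steps with layer-local mu_t, weight deposition mu_a/mu_t per
  interaction, Henyey-Greenstein scattering (E[cos theta] = g), unpolarized
  Fresnel reflection/refraction (including total internal reflection) at
  every index mismatch, Russian roulette below weight 1e-4, and a surface
  detector disk. Fluence Phi is tallied as weight x path length per voxel;
  the energy ledger (launched = absorbed + escaped) closes to <0.5% at 1e5
  packets. Compiled C++ core; bit-reproducible for a given seed.
* **SAD statistic.** SAD(z) = 100 * sum_{(x,y) in R_z} Phi(x,y,z) / sum Phi
  with R_z a 10 mm-radius region of interest at the source-detector
  midpoint, evaluated per 1 mm depth layer (by default normalized within
  the ROI cylinder, so the profile is a distribution over depth).
* **Surrogate + inversion.** Cross-head mean SAD on the 11 x 11 grid
  (SDS 19-39 mm step 2, depth 10-20 mm step 1) is fitted by Gaussian-process
  regression (squared-exponential ARD kernel, hyperparameters by maximum
  marginal likelihood) and by RBF support-vector regression for comparison;
  fits are scored by adjusted R^2 (p = 2) and leave-one-out
  cross-validation. The calibration engine scans the fitted surface on a
  0.1 mm grid with bisection refinement to answer both "SDS for a target
  depth" and "depth for a given SDS" at sensitivity levels 1-6%.

## Worked example

```r
library(fnirscal)

# head #1 of the packaged cohort: 8 / 6.8 / 5.55 mm superficial layers
ph <- build_phantom(8, 6.8, 5.55)
sim <- run_simulation(ph, sds = 29, n_photons = 1e5, seed = 7)
print(sim)
#> Monte Carlo run: sds = 29 mm, 100000 photons, seed 7
#>   detected 3 packets, total weight 0.0007123
#> Energy ledger: launched 100000 | absorbed 40042.7 | escaped 59957.3 (detected 0.000712265)
#>   closure gap -0.0191 (0.0000% of launched); roulette residual 0.0191

prof <- compute_sad_profile(sim$fluence, head = "1", sds = 29)
round(prof$sad_pct[11:16], 2)   # SAD (%) at depths 10-15 mm
#> [1] 2.78 2.08 1.60 1.16 0.86 0.57
```

The full workflow — 8 heads x 11 separations, cross-head mean SAD, GPR and
SVR surrogates, and the demonstration calibration at the 14.8 mm
dorsolateral-PFC depth — is one call:

```r
pl <- run_calibration_pipeline(n_photons = 1e5, seed = 1)
pl$scores
#>       gpr       svr
#> 0.9997617 0.9748867
print(pl$report)
#> Calibration report (sds_from_depth, input 14.8 mm): recommended separation per SAD level
#>  level_pct recommended_mm feasible sad_sd_pct
#>          1           31.3     TRUE 0.01899366
#>          2              -    FALSE         NA
#>          3              -    FALSE         NA
#>          4              -    FALSE         NA
#>          5              -    FALSE         NA
#>          6              -    FALSE         NA
```

Reading: to sense a target 14.8 mm below the scalp with at least 1% of the
midpoint-cylinder fluence in that depth layer, place the detector ~31 mm
from the source; at this photon budget the predicted sensitivity tops out
just below 2% at the longest supported separation (39 mm), so higher levels
would need a different probe or model assumptions. The GPR surrogate fits
the 121-point training grid with adjusted R^2 = 0.9998, well above the SVR
fit (0.9749), which is why the calibration engine uses it. (At production
photon budgets the mean-SAD surface is smoother and the GPR fit moves closer
to an exact interpolant; sensitivity levels up to 3% at this depth have been
reported for comparable setups.)

A command-line front end wrapping the same functions is installed at
`inst/scripts/fnirscal` (`build-phantom`, `simulate`, `analyze`, `fit`,
`calibrate`, `run-all`).

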