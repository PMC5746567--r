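# phageflow

Wall shear stress (WSS) sensing from time-lapse fluorescence images of a
wall-tethered Brownian nanorod.

## The problem

A rigid fluorescent nanorod — an M13 bacteriophage construct, about
7 nm wide and 900 nm long, bound to a surface by one end — wobbles under
Brownian rotation. An applied shear flow biases its orientation toward
the flow direction, and the strength of that bias measures the shear
stress at the wall, right where cells sense it. The dimensionless dial
is the rotational Peclet number

    Pe = gamma_dot * tau,      tau = mu * L^3 / (kB * T),

the ratio of shear-driven to Brownian rotation. Since
`WSS = mu * gamma_dot = Pe * kB * T / L^3`, an estimate of Pe converts
to wall shear stress using only temperature and rod geometry — no
viscosity needed.

The package is for experimentalists and modellers who image such
tethered-rod sensors and want a mechanistic, fully automated readout:
from raw 8-bit frames to a Peclet number and a stress in pascals.

## What it computes

1. **Hydrodynamics.** Stokes-flow resistance and mobility problems for
   a rod pivoting on a plane no-slip wall, solved with regularized
   stokeslets and a wall image system ("blakelet") that satisfies
   no-slip exactly. This yields the rotational advection vector
   `alpha(theta, phi)` (shear-driven reorientation rate) and diffusion
   matrix `D(theta)` — `compute_coefficient_table()`.
2. **Orientation statistics.** The steady Fokker–Planck equation on the
   hemisphere, `div(Pe * alpha * psi - D grad psi) = 0` with
   `integral(psi) = 1`, solved by a conservative finite-volume scheme;
   its in-plane marginal `Phi(phi; Pe)` and CDF family over
   `1 <= Pe <= 200` — `solve_steady()`, `build_family()`.
3. **Model-based image analysis.** A Gaussian-PSF forward model of the
   rod image (`render()`) and a staged global fit of
   `(x0, y0, L, phi, sigma_x, B)` per frame by sum-squared-error
   minimization (`fit_frame()`, `fit_stack()`), with optional median
   filter/background-subtraction preprocessing (`preprocess()`).
4. **Flow estimation.** The Peclet number minimizing the
   Kolmogorov–Smirnov distance between the fitted-angle sample CDF and
   the model CDF family (`estimate_peclet()`), and the conversion to
   WSS (`pe_to_wss()`).
5. **Validation.** A synthetic-image harness (`run_validation()`) that
   draws known angles from the model, renders noisy 8-bit frames,
   refits them, and summarizes accuracy (within-1°/within-5°
   percentages, success rates, Bland–Altman agreement of fitted vs true
   Pe).

## Worked example

```r
library(phageflow)

# 1. hydrodynamic coefficients and the angle-distribution family
coeffs <- compute_coefficient_table()
family <- build_family(coeffs)

# 2. simulate a time-lapse at a known flow (Pe = 60): 40 frames,
#    tether in the central +/-0.5 um, peak 255, noise N(76.5, 5)
phis <- rejection_sample(family, pe = 60, n = 40, seed = 3)
stack <- generate_frames(phis, validation_config(), seed = 4)

# 3. recover the flow from the images alone
out <- run_pipeline(stack$frames, family, run_config(seed = 3))
out$estimate$pe_hat   # fitted Peclet number
out$wss$wss_pa        # wall shear stress, pascals
```

With the defaults (T = 298.15 K, water-like viscosity, L = 0.9 um) this
prints a fitted Peclet number of 87.6 and a wall shear stress of
0.494 Pa (= `Pe * kB * T / L^3`). The true value 60 lies inside the
finite-sample scatter of a 40-frame series — the KS estimator's spread
at this sample size is of order tens of Pe, which is why the validation
study uses 180 frames per condition. The image analysis itself is far
tighter: all 40 frames fit successfully and the fitted angles track the
simulated ones with a median error of 0.35 degrees.

A command-line driver covering the same journeys (tabulate, solve,
render, fit, estimate, validate, end-to-end run) ships in
`inst/scripts/phageflow.R`.

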