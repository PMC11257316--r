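# ciket — Michaelis–Menten kinetics with competitive inhibition

`ciket` is an R toolkit for the rate equations of Michaelis–Menten enzyme
kinetics when a competing ligand binds the same active site. It covers both
the **fully competitive** scheme, in which the inhibitor is itself turned
over into a product,

```
E + S <-> ES -> E + P        (k1, k-1, k2)
E + I <-> EI -> E + Q        (ki, k-i, k3)
```

and the **partial** scheme, in which EI is a dead-end complex (`k3 = 0`).
After the scaling `S = s/s0`, `X = x/e0`, `tau = k2 t`, … the dynamics are
governed by seven dimensionless constants
(`eta_S, eta_I, eps_S, eps_I, kappa_S, kappa_I, rho`), and every quantity
the package computes is written in these terms.

The package is aimed at enzymologists and modellers who need more than the
textbook steady-state formula: it implements

* reference (adaptive) and explicit-Euler simulators for both schemes and
  for the phi-approximation linear system, with steady-state event
  detection (`dX/dtau = 0` crossings) and conservation-plane diagnostics
  (`V + P + S = 1`, `U/rho + Q + I = 1`);
* the quasi-steady-state family: classical sQSSA, the **refined sQSSA**
  with enzyme-corrected Michaelis groups
  (`v = vmax s0 / (s0 + e0 + K_MS (1 + i0/(e0 + K_MI)))`), the total QSSA
  cubic, and phase-space cubic/quadratic closures;
* the acceleration-factor ratio
  `delta = [vmax/(K_MS+e0)] / [umax/(K_MI+e0)]`, which decides which
  complex exhibits two temporally separated steady states, together with
  the closed forms for the prolonged secondary state;
* Lambert-W pre-steady-state solutions, biexponential time courses,
  reactant-depletion inversions, and all steady-state timescale formulas;
* pre/post-steady-state intersection solvers for steady reactant levels;
* error functionals of the sQSSA family (`H_S`, `H_I`, `Gamma_S`), their
  maxima in the enzyme ratio, validity-condition flags, and
  `(eps_S, eps_I)` error grids benchmarked against simulation;
* a synthetic velocity-data generator and nonlinear least-squares recovery
  of `vmax, K_MS, K_MI` (or `K_DI`), with bootstrap standard errors.

## Worked example

```r
library(ciket)

# dimensionless parameter set with a strong timescale split
p <- full_dimless(eta_S = 0.2, eps_S = 4.1, kappa_S = 3.1,
                  eta_I = 0.1, eps_I = 1.2, kappa_I = 0.1, rho = 10)
derived_ratios(p)[, c("sigma", "gamma", "delta")]
#> # A tibble: 1 × 3
#>   sigma gamma  delta
#>   <dbl> <dbl>  <dbl>
#> 1 0.171  1.55 0.0646

traj <- simulate_full(p)           # adaptive reference integrator
detect_steady_states(traj)[, c("channel", "order", "tau", "S", "I")]
#> # A tibble: 2 × 5
#>   channel   order      tau     S       I
#>   <chr>     <chr>    <dbl> <dbl>   <dbl>
#> 1 inhibitor primary 0.0273 0.786 0.242
#> 2 substrate primary 0.293  0.441 0.00887
```

The EI complex reaches its steady state at `tau_CI ≈ 0.027` while the ES
complex peaks only at `tau_CS ≈ 0.29`: with these parameters there is no
common steady state, which is why the single-steady-state textbook
formulas misestimate the velocities here.

Parameter recovery from synthetic steady-state data:

```r
truth <- dimensional_params(k1 = 100, k_m1 = 200, k2 = 1,
                            ki = 100, k_mi = 200, k3 = 1,
                            e0 = 0.005, s0 = 1, i0 = 1)   # K_MS = 2.01 M
ds <- generate_velocity_dataset(truth, s0 = c(0.5, 1, 2, 5, 10),
                                i0 = c(0.5, 2, 8), noise_sd = 0,
                                velocity_source = "simulation")
fit <- fit_velocity_model(ds, "refined", e0 = truth$e0, n_boot = 0)
tidy(fit)
#> # A tibble: 4 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 vmax   0.00500        NA
#> 2 KMS    2.01           NA
#> 3 KMI    2.01           NA
#> 4 umax   0.00500        NA
```

The refined law recovers `vmax = k2 e0 = 0.005 M/s` and
`K_MS = K_MI = 2.01 M` to three digits; the classical sQSSA fitted to the
same data at enzyme excess inflates `K_MS` several-fold (see the methods
vignette).

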