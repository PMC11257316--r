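---
title: "Models and methods: competitive-inhibition kinetics in ciket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: competitive-inhibition kinetics in ciket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciket)
```

## The model

Two ligands compete for the same enzyme active site. In the fully
competitive scheme both are substrates,

$$E+S \overset{k_1}{\underset{k_{-1}}\rightleftharpoons} ES
  \xrightarrow{k_2} E+P, \qquad
  E+I \overset{k_i}{\underset{k_{-i}}\rightleftharpoons} EI
  \xrightarrow{k_3} E+Q,$$

with mass conservation $e = e_0-x-y$, $s = s_0-x-p$, $i = i_0-y-q$. In the
partial scheme $k_3 = 0$ and EI is a dead-end complex. Scaling every
concentration by its total and time by $k_2$ ($\tau = k_2 t$) leaves seven
dimensionless constants,

$$\eta_S = \frac{k_2}{k_1 s_0},\;
  \kappa_S = \frac{k_{-1}}{k_1 s_0},\;
  \varepsilon_S = \frac{e_0}{s_0},\;
  \eta_I = \frac{k_3}{k_i i_0},\;
  \kappa_I = \frac{k_{-i}}{k_i i_0},\;
  \varepsilon_I = \frac{e_0}{i_0},\;
  \rho = \frac{k_3}{k_2},$$

with the Michaelis groups $\mu = \eta+\kappa$, their enzyme-corrected
refinements $\tilde\mu = \varepsilon+\mu$, and $\alpha = 1+\tilde\mu$.
$\eta_S$, $\eta_I$ (and $\chi_I = k_2/k_i i_0$ for the partial scheme) are
singular-perturbation parameters: they multiply the highest derivatives and
set the pre-steady-state boundary layers. All package functions work in
this dimensionless space; `nondimensionalize()` and `dimensionalize()`
convert, retaining the scale references $(s_0, i_0, e_0, k_2)$.

Exact consequences used everywhere as diagnostics: trajectories lie on the
conservation planes $V+P+S = 1$ and $U/\rho+Q+I = 1$, where
$V = \varepsilon_S X$ and $U = \rho\,\varepsilon_I Y$ are the dimensionless
velocities.

## Two steady states and the ratio delta

The complexes need not peak together. The acceleration factors
$f_S = v_{\max}/(K_{MS}+e_0)$ and $f_I = u_{\max}/(K_{MI}+e_0)$ compare the
two conversion channels; their ratio

$$\delta = \frac{f_S}{f_I}
  = \frac{\tilde\mu_I\,\varepsilon_S}{\rho\,\tilde\mu_S\,\varepsilon_I}$$

controls the phenomenology. For $\delta<1$ the EI complex turns over
faster, strips enzyme from the ES complex, and the ES time course becomes
bimodal: a transient *primary* maximum, a dip, and a prolonged *secondary*
steady state reached only after EI depletion (mirror image for
$\delta>1$; a single common steady state needs $\delta\approx 1$). The
secondary levels follow from $dV/dS = 0$ on the $\delta$-coupled
post-steady velocity: $S_C = (\delta\tilde\mu_I/(1-\delta))^{\delta}$ for
$\delta<1$ and $I_C = (\tilde\mu_S/(\delta-1))^{1/\delta}$ for $\delta>1$.
(These placements follow from re-deriving the stationary condition
symbolically; the simulation-extremum tests confirm both to within ~2%.)
As $e_0\to\infty$, $\delta\to v_{\max}/u_{\max} = 1/\rho$ (equal to 1 in
the usual $\rho = 1$ setting) — excess enzyme decouples the channels.

## Simulators

`simulate_full()`, `simulate_partial()` and `simulate_phi()` offer two
integrators:

* **reference** — `deSolve::lsoda` at `rtol = 1e-10`, `atol = 1e-12`, on a
  geometric output grid whose first point resolves the boundary layer
  (width $\sim\eta_S/\alpha_S$). This is the accuracy oracle.
* **euler** — the explicit scheme with fixed $\Delta\tau \le 10^{-5}$
  (implemented in C++; storage decimated to at most $2\times10^5$ rows).
  It exists for fidelity with the scheme the theory prescribes; the two
  integrators agree to $10^{-4}$ sup-norm on every reference set we test.

S, I and E are co-integrated as redundant states, so the conservation-plane
residuals of `conservation_residuals()` are genuine global error measures
(reference $<10^{-6}$, Euler $<10^{-3}$) rather than identities.

The default horizon is $50/\min(\varepsilon_S, \rho\varepsilon_I)$
(the slower product channel needs $\sim\varepsilon^{-1}$ to complete),
truncated once both reactants fall below $10^{-3}$; the partial scheme
stops only when, additionally, the EI channel has relaxed
($|dY/d\tau| < 10^{-7}$), because its equilibrium
$Y_\infty = (\beta_I-\sqrt{\beta_I^2-4\varepsilon_I})/2\varepsilon_I$ lags
substrate exhaustion.

`detect_steady_states()` locates $dX/d\tau = 0$ and $dY/d\tau = 0$ as sign
changes of centered differences on the stored grid, with a $10^{-12}$
dead band, a three-point persistence requirement, linear interpolation of
the crossing, and exclusion of events where the complex is below
$10^{-4}$ (terminal decay and float chatter). The first maximum per
channel is labelled primary, later maxima secondary. One caveat this
design surfaced: near a very flat extremum the *location* carries little
information — on the timescale-split reference set the ES maximum moves
X by less than 0.1% over $\tau\in[0.27, 0.33]$. The commonly quoted
event time for this setting is 0.31; our computation (two independent
integrators agreeing to $7\times10^{-6}$ in X) places the maximum at
0.293, and we report the computed value.

## The approximation family

All closed forms are exported with the conventions of the field:

* classical sQSSA `sqssa_velocity()` and the refined variant
  `refined_sqssa_velocity()` (replace $\mu$ by $\tilde\mu$; at stationary
  reactants $V_2 = \varepsilon_S(\alpha_I-1)/(\alpha_S\alpha_I-1)$), in
  both the reactant and the product spaces;
* the product-space cubic (`cubic_qssa_vpq()`) and the total-QSSA cubic
  (`tqssa_velocity()`). Both cubics were re-derived by computer algebra;
  root selection filters real roots to the physical
  box and, among survivors, takes the one nearest the refined pair
  (continuity with the small-$\varepsilon$ limit), then polishes by
  Newton steps to residuals $<10^{-10}$. The traditional closed cube-root
  expression is evaluated in complex arithmetic with a numeric fallback
  when its real limit disagrees by more than $10^{-8}$;
* the one-channel-closed post-steady branches `caseII_post_velocity()`
  (quadratics; the $(V,S)$ branch's quadratic variable is the ES
  fraction, the $(U,I)$ branch's the EI fraction, both obtained by
  computer-algebra elimination);
  these track the simulated post-steady decays to <5% on the $\delta=0.14$
  and $\delta=9$ reference sets;
* the $\delta$-expansion `taylor_delta_velocity()` (exact at $\delta=1$,
  first-order remainder verified numerically to scale as $(\delta-1)^2$);
* Lambert-W pre-steady solutions `presteady_V()`/`presteady_U()` and
  their partial-scheme analogues. The principal branch suffices: every
  argument deforms continuously from $W(-1/e) = -1$. `pracma`'s Lambert W
  does not converge for large arguments, so the package carries its own
  implementation (Halley iteration, branch-point series, log-space Newton
  for arguments beyond overflow), verified to $10^{-15}$ residual;
* biexponential time courses `biexponential_full()` (the products are the
  exact integrals of the velocity difference-of-exponentials) and the
  uncoupled closed forms `uncoupled_solutions()`, whose phase-space
  sections are computed by monotone inversion of $P(\tau)$ — the steady
  product level then *equals* the argmax of $V(P)$ by construction, the
  consistency property the theory requires;
* depletion inversions `depletion_time_courses()` with regime bands
  $\delta<0.2$, $[0.2, 5]$, $>5$ (a documented choice; the theory gives
  only the three limits). At $\delta = 1$ the inversion is exact
  (implicit-integral residual at machine level).

### What the approximations do and do not achieve

Quantified against the reference simulator:

* the W-based $(V,S)$ and $(U,I)$ phase solutions stay within 5% of the
  simulation over the pre-steady window $\tau \le \tau_{CS}/2$ in their
  validity regimes (observed ~0.2%), and satisfy their generating ODEs to
  machine accuracy away from the ill-conditioned $S\to1$ corner (where
  $dV/dP$ diverges and *numerical* differentiation of any solution
  becomes meaningless);
* the time-domain single-exponential and biexponential forms do **not**
  resolve the inner (EI) boundary layer: inside the deep pre-steady
  window they deviate by tens of percent even in validity regimes, while
  from $\tau_{CS}$ onward they agree to ~2%. Their argmax is *not* a good
  estimate of the first simulated complex maximum when the two
  exponential rates are well separated (it lands near
  $\ln(\lambda_2/\lambda_1)/\lambda_2$, an order of magnitude beyond the
  rise knee on the bimodal reference set);
* the phi-approximation (dropping the $\phi = \eta\varepsilon$ nonlinear
  terms leaves a linear system whose characteristic quartic
  `phi_quartic_coeffs()` carries the exact eigenvalues; both
  eliminations share it by construction) matches the full dynamics
  to <0.1% through the pre- and early post-steady regimes, but the late
  depletion acquires a time-lag offset (up to ~0.12 in I on the small-eps
  reference set). The gap shrinks monotonically, at least first order, as
  the $\phi$ weights are scaled down.

## Steady levels, error analysis

`full_intersection_levels()` and `partial_intersection_levels()` intersect
the pre-steady edges $V = 1-S$, $U = \rho(1-I)$ (the trajectories are
confined to those triangles) with a post-steady branch; bracketed
root-finding takes the largest root below 1, residuals are kept below
$10^{-10}$, and the $\delta = 1$ quadratics agree with the numeric roots
to $10^{-10}$. Across a ten-point $\delta\in[0.2, 6.6]$ family in a
moderate-$\varepsilon$ regime the levels track the simulated first
steady-state levels within 7% in both channels.

`error_integrals()` integrates the exponential pre-steady deficit of the
refined stationary sQSSA over one relaxation time:
$H_S = V_2\,\tau_{CS}(1-e^{-1})$, etc. Differentiating $H_S$ exactly
gives the maxima loci
$\varepsilon_{S,\max} = \mu_S+\tilde\mu_I/(1+\tilde\mu_I)$ and
$\varepsilon_{I,\max} = \mu_I+\tilde\mu_S/(1+\tilde\mu_S)$. The sufficiency ratios
$E_1 = \varepsilon_S/\varepsilon_{S,\max}$ etc. are flagged against a
default threshold of 0.1, and $\sigma,\delta$ "near 1" uses a 0.8–1.25
band; both are arguments.

`error_grid()` closes $\rho$ by $\sigma$ per cell, simulates, detects
events, and scores each approximation at stationary reactants with
$\mathrm{error}\% = 100\,|V_{sim}-V_{approx}|/V_{sim}$, where $V_{sim}$ is
the prolonged event for a multi-steady channel. Two findings from running
these grids deserve emphasis because they differ from how this theory is
usually summarized:

* refined ≤ classical holds in ~76% of cells on a $[10^{-3}, 10^2]$
  5×5 log grid, not ≥90%. The failing cells are all deep-C1 cells where
  both errors are below 0.1% and the ordering is decided by
  $O(\eta)$ terms neither expression models; wherever enzyme is not
  vanishingly dilute the refined form wins, often by orders of magnitude
  (at $\varepsilon_S = \varepsilon_I = 100$: 3240% vs 1.8%).
* the Spearman correlation of the V-channel error with $\delta$ is
  negative and of the U-channel error positive. The opposite signs are
  sometimes quoted, but the mechanism decides it: for $\delta<1$ the ES
  channel is the multi-steady one, the stationary approximation captures
  only its transient primary state, and the V-error is therefore large at
  small $\delta$ — the familiar advice to work at $\delta>1$ when
  measuring the substrate velocity says the same thing. A pair of
  acceptance expectations in the test suite encode the opposite-sign
  summary and fail; we regard the computation, which any user can rerun
  from `error_grid()`, as the trustworthy account.

## Synthetic data and parameter recovery

`generate_velocity_dataset()` emulates steady-state velocity-vs-substrate
experiments at several inhibitor levels: velocities come from the
simulated prolonged steady event (or a named closed form), with
multiplicative Gaussian noise on the relative scale truncated at −90%.
`fit_velocity_model()` fits the dimensional laws by `minpack.lm` on
log-parameters (positivity by construction) with five seeded starts and
case-resampling bootstrap standard errors. When the dataset carries both
product velocities the v- and u-laws are fitted jointly.

The deep-C1 recovery design uses $k_1 = k_i = 100$, $k_{-1} = k_{-i} =
200$, $k_2 = k_3 = 1$ (so $K_M = 2.01$ M and $\delta = 1$ exactly),
$e_0 = 0.005$ M, $s_0\in[0.5, 10]$, $i_0\in[0.5, 8]$ — concentrations of
the order of $K_M$ for identifiability while
$\varepsilon,\eta \lesssim 10^{-2}$; there the refined law matches the
simulated velocities to 0.15% and recovers $v_{\max}, K_{MS}, K_{MI}$
within 1%. The enzyme-excess comparison uses the same rates with
$e_0 = 1$ M, where the classical sQSSA's $K_{MS}$ bias is several times
the refined law's. Bootstrap coverage and $1/\sqrt{n}$ scaling are
checked by small Monte-Carlo designs (20 replicates, 60–80 resamples) —
sizes chosen to exercise the statistics, not to certify them finely.

## Numerical choices and limitations

* Radicands are clipped at $-10^{-12}$ (float noise); anything more
  negative raises a regime error.
* Root scans for "largest root in (0,1)" use a 2000-point grid before
  `uniroot` at $10^{-14}$ tolerance.
* The synthetic-data generator emulates ideal steady-state read-outs:
  no instrument baseline, no time-discretization of the assay, noise
  independent across wells. Passing recovery tests therefore show the
  estimator is consistent for the model, not that real assays are free
  of systematic error.
* Dimensional output is limited to $t = \tau/k_2$ rescaling and molar
  units; no unit parsing.
* The stochastic (single-molecule) interpretation of the rate constants
  is out of scope.
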