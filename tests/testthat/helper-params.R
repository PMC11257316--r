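# Reference parameter sets used across the test suite: the dimensionless
# study conditions, closed with sigma = 1 where rho is not fixed
# explicitly.

# delta < 1: ES complex bimodal, EI complex single-steady
ps_bimodal_S <- function() {
  close_parameters(full_dimless(0.002, 0.04, 0.2, 0.01, 0.06, 0.1), 1)
}

# delta = 9: mirror image
ps_bimodal_I <- function() {
  close_parameters(full_dimless(0.02, 0.06, 0.1, 0.003, 0.04, 0.2), 1)
}

# delta ~ 1: single steady state in both channels
ps_balanced <- function() {
  close_parameters(full_dimless(0.02, 0.06, 8.1, 0.003, 0.04, 1.2), 1)
}

# strongly split steady-state timescales (tau_CI << tau_CS), enzyme excess
ps_timescale_split <- function() {
  full_dimless(0.2, 4.1, 3.1, 0.1, 1.2, 0.1, rho = 10)
}

# small-eps set where the phi-approximation is benchmarked
ps_phi_small_eps <- function() {
  full_dimless(0.06, 0.08, 8.1, 0.03, 0.04, 1.2, rho = 1)
}

# dead-end (partial) inhibition benchmark set
ps_partial <- function() {
  partial_dimless(0.02, 0.1, 0.1, 0.03, 0.06, 0.5)
}

# moderate-eps set used for the intersection-level checks (delta = 0.244)
ps_levels <- function() {
  close_parameters(full_dimless(0.02, 0.6, 1.1, 0.03, 0.4, 0.2), 1)
}

# deep validity regime for the substrate-channel pre-steady forms
# (eps small, EI channel much faster than ES)
ps_validity_V <- function() {
  full_dimless(0.01, 0.01, 0.1, 0.001, 0.01, 0.1, rho = 1)
}

# mirror regime for the inhibitor-channel forms
ps_validity_U <- function() {
  full_dimless(0.001, 0.01, 0.1, 0.01, 0.01, 0.1, rho = 1)
}

# fully symmetric set: all channel-swapped quantities must coincide
ps_symmetric <- function(eta = 0.02, eps = 0.05, kappa = 0.5) {
  full_dimless(eta, eps, kappa, eta, eps, kappa, rho = 1)
}

# dimensional ground truth in the deep C1 regime (eta, eps all small at the
# design concentrations; K_MS = K_MI = 2.01 M, vmax = umax = 0.005 M/s)
truth_c1 <- function() {
  dimensional_params(k1 = 100, k_m1 = 200, k2 = 1, ki = 100, k_mi = 200,
                     k3 = 1, e0 = 0.005, s0 = 1, i0 = 1)
}

# same rate constants at enzyme excess (eps_S = e0/s0 up to 2)
truth_enzyme_excess <- function() {
  dimensional_params(k1 = 100, k_m1 = 200, k2 = 1, ki = 100, k_mi = 200,
                     k3 = 1, e0 = 1, s0 = 1, i0 = 1)
}

c1_design <- list(s0 = c(0.5, 1, 2, 5, 10), i0 = c(0.5, 2, 8))

# interpolate a trajectory column at given times
traj_at <- function(traj, tau, col) {
  stats::approx(traj$tau, traj[[col]], tau, rule = 2)$y
}

first_max <- function(ev, chan) {
  e <- ev[ev$channel == chan & ev$type == "maximum", ]
  e[1, ]
}

last_max <- function(ev, chan) {
  e <- ev[ev$channel == chan & ev$type == "maximum", ]
  e[nrow(e), ]
}
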