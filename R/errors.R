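# Pre-steady-state error functionals of the refined sQSSA, the loci of
# maximal error, the sufficiency conditions, and (eps_S, eps_I) error grids
# against simulation.

#' Pre-steady-state error integrals
#'
#' The refined stationary sQSSA replaces the whole pre-steady transient by
#' its plateau; integrating the exponential approach over one relaxation
#' time gives the overall error
#' `H_S = V2 tau_CS (1 - e^-1)` and `H_I = U2 tau_CI (1 - e^-1)` for the
#' fully competitive scheme, and `Gamma_S = V3 tau_CS (1 - e^-1)` for the
#' partial scheme. Both vanish as the corresponding `eps -> 0` and are
#' unimodal in `eps`, with maxima at
#' `eps_S_max = mu_S + mu_I_t/(1 + mu_I_t)` and
#' `eps_I_max = mu_I + mu_S_t/(1 + mu_S_t)` (for the partial scheme
#' `eps_S_max = mu_S + (eps_I + kappa_I)/(1 + eps_I + kappa_I)`), the exact
#' stationary points of the error functionals.
#'
#' @param p A closed `ciket_full_dimless` or a `ciket_partial_dimless`
#'   object.
#' @return A one-row tibble: `H_S, H_I, eps_S_max, eps_I_max` (full) or
#'   `Gamma_S, eps_S_max` (partial).
#' @export
error_integrals <- function(p) {
  f <- 1 - exp(-1)
  if (inherits(p, "ciket_partial_dimless")) {
    g <- .drp(p)
    V3 <- p$eps_S * (g$beta_I - 1) / (g$alpha_S * g$beta_I - 1)
    tau_CS <- p$eta_S * g$beta_I / (g$alpha_S * g$beta_I - 1)
    ek <- p$eps_I + p$kappa_I
    return(tibble::tibble(Gamma_S = V3 * tau_CS * f,
                          eps_S_max = g$mu_S + ek / (1 + ek)))
  }
  dr <- .dr(p)
  den <- dr$alpha_S * dr$alpha_I - 1
  V2 <- p$eps_S * (dr$alpha_I - 1) / den
  U2 <- p$rho * p$eps_I * (dr$alpha_S - 1) / den
  tau_CS <- dr$alpha_I * p$eta_S / den
  tau_CI <- dr$alpha_S * p$eta_I / den
  tibble::tibble(
    H_S = V2 * tau_CS * f,
    H_I = U2 * tau_CI * f,
    eps_S_max = dr$mu_S + dr$mu_I_t / (1 + dr$mu_I_t),
    eps_I_max = dr$mu_I + dr$mu_S_t / (1 + dr$mu_S_t))
}

#' Validity conditions of the sQSSA family
#'
#' Numeric left-hand sides and boolean flags of the sufficiency conditions:
#' * fully competitive: C1 (`eta_S, eta_I, eps_S, eps_I` all small), C2
#'   (stationary reactants; recorded as a statement, always applied), C3/C4
#'   (`E1 = eps_S/eps_S_max` and `E2 = eps_I/eps_I_max` small), C5 (`sigma`
#'   and `delta` both near 1), plus the timescale-matching `psi`;
#' * partial: G1 (`eta_S, chi_I, eps_S, eps_I` small), G3
#'   (`E3 = eps_S/eps_S_max` small), plus the matching ratio `xi`.
#'
#' @param p A closed `ciket_full_dimless` or `ciket_partial_dimless` object.
#' @param small Threshold below which a "much smaller than one" inequality
#'   is flagged true (default 0.1).
#' @param ratio_band Multiplicative band for the "near one" conditions; a
#'   ratio r passes when `1/ratio_band <= r <= ratio_band` (default 1.25).
#' @return A one-row tibble of values and logical flags.
#' @export
validity_conditions <- function(p, small = 0.1, ratio_band = 1.25) {
  near1 <- function(r) r >= 1 / ratio_band & r <= ratio_band
  if (inherits(p, "ciket_partial_dimless")) {
    ei <- error_integrals(p)
    E3 <- p$eps_S / ei$eps_S_max
    G1_val <- max(p$eta_S, p$chi_I, p$eps_S, p$eps_I)
    xi <- timescales_partial(p)$xi
    return(tibble::tibble(G1_value = G1_val, G1 = G1_val < small,
                          E3 = E3, G3 = E3 < small,
                          xi = xi, xi_near_1 = near1(xi)))
  }
  dr <- .dr(p)
  ei <- error_integrals(p)
  E1 <- p$eps_S / ei$eps_S_max
  E2 <- p$eps_I / ei$eps_I_max
  C1_val <- max(p$eta_S, p$eta_I, p$eps_S, p$eps_I)
  tibble::tibble(
    C1_value = C1_val, C1 = C1_val < small,
    E1 = E1, C3 = E1 < small,
    E2 = E2, C4 = E2 < small,
    sigma = dr$sigma, delta = dr$delta,
    C5 = near1(dr$sigma) && near1(dr$delta),
    psi = dr$psi, psi_near_1 = near1(dr$psi))
}

#' Steady-state velocity error grid against simulation
#'
#' For each cell of an `(eps_S, eps_I)` grid the parameter set is closed by
#' fixing `sigma`, the full scheme is simulated with the reference
#' integrator, steady-state events are detected, and each requested
#' approximation is evaluated at stationary reactants and scored with
#' `error% = 100 |V_sim - V_approx| / V_sim`. For a channel with multiple
#' steady states the prolonged (last) maximum is the reference velocity —
#' the full-fledged steady state — while a single-steady channel uses its
#' unique event. Per-cell `delta`, `E1` and `E2` are recorded.
#'
#' @param p_base A `ciket_full_dimless` object providing `eta_S, kappa_S,
#'   eta_I, kappa_I` (its eps values are overridden cell by cell).
#' @param eps_S,eps_I Grid axes (strictly increasing; default 5-point
#'   log-spaced over `[1e-3, 1e2]`).
#' @param approximations Character subset of `c("sqssa", "refined",
#'   "tqssa")`.
#' @param sigma Closure value for the rate ratio (default 1).
#' @param n_out Stored points per cell simulation.
#' @return A tibble with one row per cell: axes, `delta, E1, E2`, simulated
#'   velocities, and `errV_<id>` / `errU_<id>` percentage columns; class
#'   `ciket_error_grid`. Cells whose simulation fails are returned with NA
#'   scores rather than failing the grid.
#' @export
error_grid <- function(p_base, eps_S = 10^seq(-3, 2, length.out = 5),
                       eps_I = 10^seq(-3, 2, length.out = 5),
                       approximations = c("sqssa", "refined"),
                       sigma = 1, n_out = 1500) {
  stopifnot(inherits(p_base, "ciket_full_dimless"))
  approximations <- match.arg(approximations,
                              c("sqssa", "refined", "tqssa"), several.ok = TRUE)
  if (is.unsorted(eps_S, strictly = TRUE) ||
      is.unsorted(eps_I, strictly = TRUE)) {
    stop("grid axes must be strictly increasing", call. = FALSE)
  }
  cells <- tidyr::expand_grid(eps_S = eps_S, eps_I = eps_I)
  rows <- purrr::pmap(cells, function(eps_S, eps_I) {
    q <- p_base
    q$eps_S <- eps_S
    q$eps_I <- eps_I
    q <- close_parameters(q, sigma = sigma)
    vc <- validity_conditions(q)
    base <- tibble::tibble(eps_S = eps_S, eps_I = eps_I,
                           delta = vc$delta, E1 = vc$E1, E2 = vc$E2)
    sim <- tryCatch({
      traj <- simulate_full(q, n_out = n_out)
      ev <- detect_steady_states(traj)
      mx <- dplyr::filter(ev, .data$type == "maximum")
      pick <- function(chan) {
        e <- dplyr::filter(mx, .data$channel == chan)
        if (!nrow(e)) return(NA_real_)
        if (chan == "substrate") e$V[nrow(e)] else e$U[nrow(e)]
      }
      c(V = pick("substrate"), U = pick("inhibitor"))
    }, error = function(e) c(V = NA_real_, U = NA_real_))
    base$V_sim <- sim[["V"]]; base$U_sim <- sim[["U"]]
    for (id in approximations) {
      ap <- switch(id,
        sqssa = sqssa_velocity(q, stationary = TRUE)[, c("V", "U")],
        refined = refined_sqssa_velocity(q, stationary = TRUE)[, c("V", "U")],
        tqssa = tryCatch(tqssa_velocity(q)[, c("V", "U")],
                         error = function(e)
                           tibble::tibble(V = NA_real_, U = NA_real_)))
      base[[paste0("errV_", id)]] <-
        100 * abs(sim[["V"]] - ap$V) / sim[["V"]]
      base[[paste0("errU_", id)]] <-
        100 * abs(sim[["U"]] - ap$U) / sim[["U"]]
    }
    base
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ciket_error_grid", class(out))
  attr(out, "approximations") <- approximations
  attr(out, "sigma") <- sigma
  out
}
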