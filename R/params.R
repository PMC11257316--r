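#' Dimensional rate-constant and concentration set
#'
#' Bundles the six rate constants of the competitive-inhibition reaction
#' network together with the total enzyme, substrate and inhibitor
#' concentrations. `k3 = 0` identifies the partial (dead-end complex) scheme,
#' in which the inhibitor is never converted to a product.
#'
#' @param k1,ki Forward bimolecular binding rate constants for E+S and E+I
#'   (1/M/s).
#' @param k_m1,k_mi Dissociation rate constants of the ES and EI complexes
#'   (1/s).
#' @param k2,k3 Product-formation rate constants of the ES and EI complexes
#'   (1/s); `k3 = 0` selects the partial scheme.
#' @param e0,s0,i0 Total enzyme, substrate and inhibitor concentrations (M).
#'
#' @return An object of class `ciket_dimensional` (a named list).
#' @examples
#' d <- dimensional_params(k1 = 1, k_m1 = 1, k2 = 2, ki = 1, k_mi = 1, k3 = 1,
#'                         e0 = 1, s0 = 10, i0 = 5)
#' nondimensionalize(d)
#' @export
dimensional_params <- function(k1, k_m1, k2, ki, k_mi, k3, e0, s0, i0) {
  vals <- c(k1 = k1, k_m1 = k_m1, k2 = k2, ki = ki, k_mi = k_mi, k3 = k3,
            e0 = e0, s0 = s0, i0 = i0)
  if (any(!is.finite(vals))) {
    stop("all dimensional parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals[c("k1", "k_m1", "k2", "ki", "k_mi")] < 0) || k3 < 0) {
    stop("rate constants must be nonnegative", call. = FALSE)
  }
  if (any(vals[c("e0", "s0", "i0")] <= 0)) {
    stop("e0, s0 and i0 must be strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "ciket_dimensional")
}

#' Dimensionless parameter set of the fully competitive scheme
#'
#' The seven dimensionless constants that fully parameterize the scaled rate
#' equations of the fully competitive scheme: `eta_S = k2/(k1 s0)`,
#' `eta_I = k3/(ki i0)`, `eps_S = e0/s0`, `eps_I = e0/i0`,
#' `kappa_S = k_m1/(k1 s0)`, `kappa_I = k_mi/(ki i0)` and `rho = k3/k2`.
#'
#' @param eta_S,eta_I Singular perturbation parameters (scaled K_R values).
#' @param eps_S,eps_I Enzyme-to-substrate and enzyme-to-inhibitor ratios.
#' @param kappa_S,kappa_I Scaled dissociation constants.
#' @param rho Ratio of product-formation rates `k3/k2` (`NA` to be closed
#'   later with [close_parameters()]).
#' @return An object of class `ciket_full_dimless`.
#' @seealso [derived_ratios()], [close_parameters()], [simulate_full()]
#' @export
full_dimless <- function(eta_S, eps_S, kappa_S, eta_I, eps_I, kappa_I,
                         rho = NA_real_) {
  vals <- c(eta_S = eta_S, eps_S = eps_S, kappa_S = kappa_S,
            eta_I = eta_I, eps_I = eps_I, kappa_I = kappa_I)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("eta, eps and kappa parameters must be strictly positive",
         call. = FALSE)
  }
  if (!is.na(rho) && rho <= 0) {
    stop("rho must be strictly positive (or NA pending closure)",
         call. = FALSE)
  }
  structure(c(as.list(vals), list(rho = rho)), class = "ciket_full_dimless")
}

#' Dimensionless parameter set of the partial competitive scheme
#'
#' In the partial scheme the inhibitor forms a dead-end complex (`k3 = 0`),
#' so `eta_I` is undefined and the singular parameter of the inhibitor
#' channel is `chi_I = k2/(ki i0)`.
#'
#' @param eta_S,eps_S,kappa_S As in [full_dimless()].
#' @param chi_I Singular perturbation parameter of the inhibitor channel.
#' @param eps_I,kappa_I Enzyme-to-inhibitor ratio and scaled EI dissociation
#'   constant.
#' @return An object of class `ciket_partial_dimless`, carrying the derived
#'   `beta_I = 1 + eps_I + kappa_I` and `kappa_I_t = eps_I + kappa_I`.
#' @export
partial_dimless <- function(eta_S, eps_S, kappa_S, chi_I, eps_I, kappa_I) {
  vals <- c(eta_S = eta_S, eps_S = eps_S, kappa_S = kappa_S,
            chi_I = chi_I, eps_I = eps_I, kappa_I = kappa_I)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all partial-scheme parameters must be strictly positive",
         call. = FALSE)
  }
  out <- as.list(vals)
  out$kappa_I_t <- eps_I + kappa_I
  out$beta_I <- 1 + out$kappa_I_t
  structure(out, class = "ciket_partial_dimless")
}

#' @export
print.ciket_dimensional <- function(x, ...) {
  cat("<dimensional parameters>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.ciket_full_dimless <- function(x, ...) {
  cat("<dimensionless parameters, fully competitive scheme>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.ciket_partial_dimless <- function(x, ...) {
  cat("<dimensionless parameters, partial competitive scheme>\n")
  print(unlist(x))
  invisible(x)
}

#' Convert dimensional parameters to the dimensionless representation
#'
#' Applies the scaling `eta_S = k2/(k1 s0)`, `kappa_S = k_m1/(k1 s0)`,
#' `eps_S = e0/s0` (and the inhibitor-channel analogues) and stores the scale
#' references `s0, i0, e0, k2` as an attribute so that [dimensionalize()] can
#' invert the map. A dimensional set with `k3 = 0` routes to the partial
#' scheme, where the inhibitor singular parameter is `chi_I = k2/(ki i0)`.
#'
#' @param d A [dimensional_params()] object.
#' @return A `ciket_full_dimless` or (for `k3 = 0`) `ciket_partial_dimless`
#'   object with attribute `"scales"`.
#' @export
nondimensionalize <- function(d) {
  stopifnot(inherits(d, "ciket_dimensional"))
  scales <- c(s0 = d$s0, i0 = d$i0, e0 = d$e0, k2 = d$k2)
  if (d$k3 == 0) {
    p <- partial_dimless(
      eta_S = d$k2 / (d$k1 * d$s0), eps_S = d$e0 / d$s0,
      kappa_S = d$k_m1 / (d$k1 * d$s0),
      chi_I = d$k2 / (d$ki * d$i0), eps_I = d$e0 / d$i0,
      kappa_I = d$k_mi / (d$ki * d$i0))
  } else {
    p <- full_dimless(
      eta_S = d$k2 / (d$k1 * d$s0), eps_S = d$e0 / d$s0,
      kappa_S = d$k_m1 / (d$k1 * d$s0),
      eta_I = d$k3 / (d$ki * d$i0), eps_I = d$e0 / d$i0,
      kappa_I = d$k_mi / (d$ki * d$i0),
      rho = d$k3 / d$k2)
  }
  attr(p, "scales") <- scales
  p
}

#' Recover dimensional parameters from a dimensionless set
#'
#' Inverse of [nondimensionalize()] given the scale references.
#'
#' @param p A dimensionless parameter object.
#' @param s0,i0,e0,k2 Scale references; default to the `"scales"` attribute
#'   recorded by [nondimensionalize()].
#' @return A `ciket_dimensional` object.
#' @export
dimensionalize <- function(p, s0 = NULL, i0 = NULL, e0 = NULL, k2 = NULL) {
  sc <- attr(p, "scales")
  s0 <- s0 %||% sc[["s0"]]; i0 <- i0 %||% sc[["i0"]]
  e0 <- e0 %||% sc[["e0"]]; k2 <- k2 %||% sc[["k2"]]
  if (is.null(s0) || is.null(i0) || is.null(e0) || is.null(k2)) {
    stop("scale references s0, i0, e0, k2 are required", call. = FALSE)
  }
  if (inherits(p, "ciket_partial_dimless")) {
    k1 <- k2 / (p$eta_S * s0)
    ki <- k2 / (p$chi_I * i0)
    dimensional_params(k1 = k1, k_m1 = p$kappa_S * k1 * s0, k2 = k2,
                       ki = ki, k_mi = p$kappa_I * ki * i0, k3 = 0,
                       e0 = e0, s0 = s0, i0 = i0)
  } else if (inherits(p, "ciket_full_dimless")) {
    k3 <- p$rho * k2
    k1 <- k2 / (p$eta_S * s0)
    ki <- k3 / (p$eta_I * i0)
    dimensional_params(k1 = k1, k_m1 = p$kappa_S * k1 * s0, k2 = k2,
                       ki = ki, k_mi = p$kappa_I * ki * i0, k3 = k3,
                       e0 = e0, s0 = s0, i0 = i0)
  } else {
    stop("not a dimensionless parameter object", call. = FALSE)
  }
}

#' Derived dimensionless ratios
#'
#' Computes every derived constant used by the closed-form theory: the rate
#' ratios `sigma = k1/ki`, `gamma = k_m1/k_mi`, `rho`; the Michaelis-type
#' groups `mu = eta + kappa` and their enzyme-corrected refinements
#' `mu_t = eps + mu`; `alpha = 1 + mu_t`; the acceleration factors
#' `f_S = eps_S/mu_S_t`, `f_I = rho eps_I/mu_I_t` (dimensionless forms of
#' `v_max/(K_MS+e0)` and `u_max/(K_MI+e0)`, up to the common `k2` scale) and
#' their ratio `delta = f_S/f_I`, which governs which complex exhibits
#' multiple steady states; the nonlinearity weights `phi = eta * eps`; and
#' the timescale-matching ratio `psi = alpha_I eta_S / (alpha_S eta_I)`.
#'
#' `delta` is evaluated both as `mu_I_t eps_S / (rho mu_S_t eps_I)` and as
#' `f_S/f_I`; the two agree to machine precision by construction and the
#' identity `gamma/sigma = eps_I kappa_S / (eps_S kappa_I) = K_DS/K_DI`
#' links the rate ratios.
#'
#' @param p A `ciket_full_dimless` object with `rho` set.
#' @return A one-row tibble of all derived ratios.
#' @examples
#' p <- full_dimless(0.002, 0.04, 0.2, 0.01, 0.06, 0.1)
#' p <- close_parameters(p, sigma = 1)
#' derived_ratios(p)$delta  # 0.1405 at 4 significant figures
#' @export
derived_ratios <- function(p) {
  stopifnot(inherits(p, "ciket_full_dimless"))
  if (is.na(p$rho)) {
    stop("rho is not set; close it first with close_parameters()",
         call. = FALSE)
  }
  if (p$rho == 0) {
    stop("rho = 0 identifies the partial scheme: delta is undefined there",
         call. = FALSE)
  }
  mu_S <- p$eta_S + p$kappa_S
  mu_I <- p$eta_I + p$kappa_I
  mu_S_t <- p$eps_S + mu_S
  mu_I_t <- p$eps_I + mu_I
  f_S <- p$eps_S / mu_S_t
  f_I <- p$rho * p$eps_I / mu_I_t
  tibble::tibble(
    sigma = p$eta_I * p$eps_S / (p$rho * p$eta_S * p$eps_I),
    gamma = p$eta_I * p$kappa_S / (p$rho * p$eta_S * p$kappa_I),
    rho = p$rho,
    delta = mu_I_t * p$eps_S / (p$rho * mu_S_t * p$eps_I),
    f_S = f_S, f_I = f_I,
    mu_S = mu_S, mu_I = mu_I,
    mu_S_t = mu_S_t, mu_I_t = mu_I_t,
    alpha_S = 1 + mu_S_t, alpha_I = 1 + mu_I_t,
    phi_S = p$eta_S * p$eps_S, phi_I = p$eta_I * p$eps_I,
    psi = (1 + mu_I_t) * p$eta_S / ((1 + mu_S_t) * p$eta_I),
    eps_IS = p$eps_I / p$eps_S
  )
}

#' Close the parameter set by fixing sigma
#'
#' The six free dimensionless parameters leave one rate ratio undetermined;
#' fixing `sigma = sigma_f` closes `rho` via
#' `rho = eta_I eps_S / (sigma_f eta_S eps_I)` (and thereby `gamma`).
#'
#' @param p A `ciket_full_dimless` object (its `rho`, if any, is replaced).
#' @param sigma Target value of `sigma = k1/ki`; default 1 (diffusion-limited
#'   binding of similarly sized ligands).
#' @return The parameter set with `rho` set so that
#'   `derived_ratios(p)$sigma == sigma`.
#' @export
close_parameters <- function(p, sigma = 1) {
  stopifnot(inherits(p, "ciket_full_dimless"))
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be strictly positive", call. = FALSE)
  }
  p$rho <- p$eta_I * p$eps_S / (sigma * p$eta_S * p$eps_I)
  p
}

#' delta under enzyme-excess scaling
#'
#' Evaluates `delta` with both `eps_S` and `eps_I` multiplied by each factor
#' of an increasing sequence, tracing the enzyme-excess limit
#' (`e0 -> Inf` scales both eps together). In dimensional terms
#' `delta = (vmax/(K_MS+e0)) / (umax/(K_MI+e0)) -> vmax/umax = 1/rho`,
#' which equals 1 in the usual `rho = 1` setting: excess enzyme decouples
#' the channels.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param e0_scale Increasing sequence of multiplicative factors applied to
#'   `eps_S` and `eps_I`.
#' @return A tibble with columns `scale` and `delta`.
#' @export
delta_limit_check <- function(p, e0_scale = 10^(0:6)) {
  stopifnot(inherits(p, "ciket_full_dimless"))
  if (is.unsorted(e0_scale, strictly = TRUE)) {
    stop("e0_scale must be strictly increasing", call. = FALSE)
  }
  delta <- purrr::map_dbl(e0_scale, function(f) {
    q <- p
    q$eps_S <- p$eps_S * f
    q$eps_I <- p$eps_I * f
    derived_ratios(q)$delta
  })
  tibble::tibble(scale = e0_scale, delta = delta)
}

# internal: derived ratios as a plain list (used throughout the closed forms)
.dr <- function(p) as.list(derived_ratios(p))

# internal: partial-scheme derived groups
.drp <- function(pp) {
  mu_S <- pp$eta_S + pp$kappa_S
  list(mu_S = mu_S, mu_S_t = pp$eps_S + mu_S,
       alpha_S = 1 + pp$eps_S + mu_S,
       kappa_I_t = pp$kappa_I_t, beta_I = pp$beta_I,
       phi_S = pp$eta_S * pp$eps_S)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
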