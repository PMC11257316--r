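# Pre-steady-state and time-domain approximations: Lambert-W phase-space
# solutions, biexponential time courses, uncoupled closed forms, and the
# steady-state timescale formulas.

#' Principal-branch Lambert W with domain clamping
#'
#' All phase-space inversions here are continuous deformations of the
#' initial point `W(-1/e) = -1`, so the principal branch applies throughout;
#' arguments that undershoot `-1/e` by rounding (within `1e-12`) are clamped.
#'
#' @param z Numeric vector, `z >= -1/e - 1e-12`.
#' @return `W0(z)`.
#' @export
lambert_w0 <- function(z) {
  lo <- -exp(-1)
  if (any(z < lo - 1e-12)) {
    stop("Lambert W argument below -1/e: outside the principal branch",
         call. = FALSE)
  }
  vapply(pmax(z, lo), .w0_scalar, 0)
}

# principal branch by Halley iteration; branch-point series start near -1/e,
# asymptotic log start for large arguments
.w0_scalar <- function(z) {
  if (z == 0) return(0)
  if (z <= -exp(-1) + 1e-300) return(-1)
  if (z < 0) {
    p <- sqrt(2 * (exp(1) * z + 1))
    w <- -1 + p - p^2 / 3 + 11 * p^3 / 72
    if (w >= 0) w <- -1e-10
  } else if (z > exp(2)) {
    L <- log(z)
    w <- L - log(L)
  } else {
    w <- z / (1 + z)
  }
  for (i in 1:50) {
    ew <- exp(w)
    f <- w * ew - z
    d <- f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
    if (!is.finite(d)) break
    w <- w - d
    if (abs(d) <= 1e-15 * (abs(w) + 1e-300)) break
  }
  w
}

# internal: W0(exp(L)) evaluated stably for arbitrarily large L (the
# phase-space exponents overflow exp() long before W itself is large)
.lambert_w0_exp <- function(L) {
  vapply(L, function(l) {
    if (l < 2) return(.w0_scalar(exp(l)))
    w <- l - log(l)
    for (i in 1:100) {
      # Newton on w + log(w) = l
      d <- (w + log(w) - l) * w / (w + 1)
      w <- w - d
      if (abs(d) < 1e-15 * w) break
    }
    w
  }, 0)
}

# internal: pre-steady constants of the substrate channel (case I/II forms)
.pre_const_V <- function(p) {
  dr <- .dr(p)
  list(a = (dr$alpha_S * dr$alpha_I - 1) / (p$eta_S * dr$alpha_I),
       b = (dr$alpha_I - 1) / (p$eta_S^3 * dr$alpha_I),
       V2 = p$eps_S * (dr$alpha_I - 1) / (dr$alpha_S * dr$alpha_I - 1))
}

.pre_const_U <- function(p) {
  dr <- .dr(p)
  list(g = p$rho * (dr$alpha_S * dr$alpha_I - 1) / (p$eta_I * dr$alpha_S),
       h = p$rho^2 * (dr$alpha_S - 1) / (p$eta_I^3 * dr$alpha_S),
       U2 = p$rho * p$eps_I * (dr$alpha_S - 1) /
         (dr$alpha_S * dr$alpha_I - 1))
}

#' Pre-steady-state substrate velocity (fully competitive scheme)
#'
#' Closed pre-steady forms for the substrate channel, all converging to the
#' plateau `V2 = eps_S (alpha_I - 1)/(alpha_S alpha_I - 1)`:
#' * in time, `V = V2 (1 - exp(-a tau))`;
#' * against product, `V = V2 (1 + W(-exp(-1 - a^2 P / (b eps_S eta_S^2))))`
#'   (so `V(P=0) = 0` via `W(-1/e) = -1`);
#' * against substrate,
#'   `V = V2 (1 - W((a-1) exp(a-1 + a^2 (S-1)/(b eps_S eta_S^2)))/(a-1))`,
#'   whose expansion near `S = 1` is `V = 1 - S + O((S-1)^2)` — the
#'   pre-steady trajectories hug the `V = 1 - S` edge of the phase triangle.
#' Here `a = (alpha_S alpha_I - 1)/(eta_S alpha_I)`,
#' `b = (alpha_I - 1)/(eta_S^3 alpha_I)`.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param tau,P,S Supply exactly one coordinate (vectorized).
#' @return A tibble with the coordinate and `V`.
#' @export
presteady_V <- function(p, tau = NULL, P = NULL, S = NULL) {
  k <- .pre_const_V(p)
  given <- sum(!is.null(tau), !is.null(P), !is.null(S))
  if (given != 1) stop("supply exactly one of tau, P, S", call. = FALSE)
  if (!is.null(tau)) {
    tibble::tibble(tau = tau, V = k$V2 * (1 - exp(-k$a * tau)))
  } else if (!is.null(P)) {
    arg <- -exp(-1 - k$a^2 * P / (k$b * p$eps_S * p$eta_S^2))
    tibble::tibble(P = P, V = k$V2 * (1 + lambert_w0(arg)))
  } else {
    R <- k$a - 1
    w <- .lambert_w0_exp(log(R) + R +
                           k$a^2 * (S - 1) / (k$b * p$eps_S * p$eta_S^2))
    tibble::tibble(S = S, V = k$V2 * (1 - w / R))
  }
}

#' Pre-steady-state inhibitor velocity (fully competitive scheme)
#'
#' Mirror of [presteady_V()] for the inhibitor channel with
#' `g = rho (alpha_S alpha_I - 1)/(eta_I alpha_S)`,
#' `h = rho^2 (alpha_S - 1)/(eta_I^3 alpha_S)` and plateau
#' `U2 = rho eps_I (alpha_S - 1)/(alpha_S alpha_I - 1)`; near `I = 1` the
#' `(U, I)` solution satisfies `U = rho (1 - I) + O((I-1)^2)`.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param tau,Q,I Supply exactly one coordinate (vectorized).
#' @return A tibble with the coordinate and `U`.
#' @export
presteady_U <- function(p, tau = NULL, Q = NULL, I = NULL) {
  k <- .pre_const_U(p)
  given <- sum(!is.null(tau), !is.null(Q), !is.null(I))
  if (given != 1) stop("supply exactly one of tau, Q, I", call. = FALSE)
  if (!is.null(tau)) {
    tibble::tibble(tau = tau, U = k$U2 * (1 - exp(-k$g * tau)))
  } else if (!is.null(Q)) {
    arg <- -exp(-1 - k$g^2 * Q / (k$h * p$eps_I * p$eta_I^2))
    tibble::tibble(Q = Q, U = k$U2 * (1 + lambert_w0(arg)))
  } else {
    R <- (k$g - p$rho) / p$rho
    w <- .lambert_w0_exp(log(R) + R +
                           k$g^2 * (I - 1) / (k$h * p$eps_I * p$eta_I^2))
    tibble::tibble(I = I, U = k$U2 * (1 - w / R))
  }
}

#' Biexponential time-domain solutions and the four timescales
#'
#' In the regime `(eps_I, eta_I, phi_S) -> 0` (and its mirror) each channel
#' obeys a damped linear second-order equation whose velocity is a
#' difference of two exponentials,
#' `V = (c eps_S eta_S^2/sqrt(a^2-4b)) (exp(-lambda_1 tau) -
#' exp(-lambda_2 tau))` with `lambda = (a -/+ sqrt(a^2-4b))/2`, and the
#' product is its exact integral. The reciprocal rates are the pre- and
#' post-steady timescales `tau_S1 = 1/lambda_2`, `tau_S2 = 1/lambda_1`
#' (`tau_I1`, `tau_I2` for the inhibitor channel) with separation ratios
#' `delta_tau = tau_1/tau_2`.
#'
#' @param p A closed `ciket_full_dimless` object in the overdamped regime
#'   (`a^2 > 4b` and `r^2 > 4g`; complex exponents raise an error).
#' @param tau Times (vectorized).
#' @return A tibble `tau, V, P, U, Q`; the timescales are available from
#'   [timescales()].
#' @export
biexponential_full <- function(p, tau) {
  k <- .biexp_const(p)
  V <- k$AV * (exp(-k$l1S * tau) - exp(-k$l2S * tau))
  P <- k$AV * ((1 - exp(-k$l1S * tau)) / k$l1S -
                 (1 - exp(-k$l2S * tau)) / k$l2S)
  U <- k$AU * (exp(-k$l1I * tau) - exp(-k$l2I * tau))
  Q <- k$AU * ((1 - exp(-k$l1I * tau)) / k$l1I -
                 (1 - exp(-k$l2I * tau)) / k$l2I)
  tibble::tibble(tau = tau, V = V, P = P, U = U, Q = Q)
}

.biexp_const <- function(p) {
  dr <- .dr(p)
  a <- (dr$alpha_S * dr$alpha_I - 1) / (p$eta_S * dr$alpha_I)
  b <- p$eps_S / p$eta_S
  cc <- (dr$alpha_I - 1) / (p$eta_S^3 * dr$alpha_I)
  r <- p$rho * (dr$alpha_S * dr$alpha_I - 1) / (p$eta_I * dr$alpha_S)
  g <- p$eps_I * p$rho^2 / p$eta_I
  d <- p$rho^2 * (dr$alpha_S - 1) / (p$eta_I^3 * dr$alpha_S)
  if (a^2 <= 4 * b || r^2 <= 4 * g) {
    stop("complex-exponent (underdamped) regime: a^2 <= 4b or r^2 <= 4g",
         call. = FALSE)
  }
  DS <- sqrt(a^2 - 4 * b); DI <- sqrt(r^2 - 4 * g)
  list(a = a, b = b, cc = cc, r = r, g = g, d = d,
       l1S = (a - DS) / 2, l2S = (a + DS) / 2,
       l1I = (r - DI) / 2, l2I = (r + DI) / 2,
       AV = cc * p$eps_S * p$eta_S^2 / DS,
       AU = d * p$eps_I * p$eta_I^2 / DI)
}

#' Closed-form solutions under uncoupled conditions
#'
#' When the channels decouple (`kappa_S, kappa_I -> Inf`, or no inhibition)
#' each product obeys an independent damped oscillator driven to 1:
#' `P(tau) = 1 - (lambda_2 e^{-lambda_1 tau} - lambda_1 e^{-lambda_2 tau}) /
#' (lambda_2 - lambda_1)` with
#' `lambda = (alpha_S -/+ sqrt(alpha_S^2 - 4 eps_S eta_S))/(2 eta_S)` (and
#' the inhibitor analogue with rates scaled by rho). Velocities are the
#' exact derivatives. Phase-space sections `V(P)`/`U(Q)` are obtained by
#' monotone inversion of `P(tau)` (bracketed root-finding), and the steady
#' product levels from the analytic argmax times.
#'
#' @param p A closed `ciket_full_dimless` object with
#'   `alpha_S^2 > 4 eps_S eta_S` (real exponents).
#' @param tau,P,Q Supply exactly one coordinate (vectorized).
#' @return A tibble with `tau, P, Q, V, U, S, I` (time mode) or the phase
#'   section requested.
#' @export
uncoupled_solutions <- function(p, tau = NULL, P = NULL, Q = NULL) {
  k <- .uncoupled_const(p)
  given <- sum(!is.null(tau), !is.null(P), !is.null(Q))
  if (given != 1) stop("supply exactly one of tau, P, Q", call. = FALSE)
  Pt <- function(t) 1 - (k$l2S * exp(-k$l1S * t) - k$l1S * exp(-k$l2S * t)) /
    (k$l2S - k$l1S)
  Vt <- function(t) k$l1S * k$l2S / (k$l2S - k$l1S) *
    (exp(-k$l1S * t) - exp(-k$l2S * t))
  Qt <- function(t) 1 - (k$l2I * exp(-k$l1I * t) - k$l1I * exp(-k$l2I * t)) /
    (k$l2I - k$l1I)
  Ut <- function(t) k$l1I * k$l2I / (k$l2I - k$l1I) *
    (exp(-k$l1I * t) - exp(-k$l2I * t))
  if (!is.null(tau)) {
    P <- Pt(tau); V <- Vt(tau); Q <- Qt(tau); U <- Ut(tau)
    return(tibble::tibble(tau = tau, P = P, Q = Q, V = V, U = U,
                          S = 1 - V - P, I = 1 - U / p$rho - Q))
  }
  invert <- function(fun, y) {
    vapply(y, function(yy) {
      if (yy <= 0) return(0)
      if (yy >= 1) return(Inf)
      hi <- 1
      while (fun(hi) < yy) hi <- hi * 2
      stats::uniroot(function(t) fun(t) - yy, c(0, hi), tol = 1e-12)$root
    }, 0)
  }
  if (!is.null(P)) {
    stopifnot(all(P >= 0 & P < 1))
    tau <- invert(Pt, P)
    tibble::tibble(P = P, tau = tau, V = Vt(tau))
  } else {
    stopifnot(all(Q >= 0 & Q < 1))
    tau <- invert(Qt, Q)
    tibble::tibble(Q = Q, tau = tau, U = Ut(tau))
  }
}

.uncoupled_const <- function(p) {
  dr <- .dr(p)
  aS <- dr$alpha_S; aI <- dr$alpha_I
  dS2 <- aS^2 - 4 * p$eps_S * p$eta_S
  dI2 <- aI^2 - 4 * p$eps_I * p$eta_I
  if (dS2 <= 0 || dI2 <= 0) {
    stop("complex exponents: alpha^2 <= 4 eps eta", call. = FALSE)
  }
  list(l1S = (aS - sqrt(dS2)) / (2 * p$eta_S),
       l2S = (aS + sqrt(dS2)) / (2 * p$eta_S),
       l1I = p$rho * (aI - sqrt(dI2)) / (2 * p$eta_I),
       l2I = p$rho * (aI + sqrt(dI2)) / (2 * p$eta_I))
}

#' Steady-state values of the uncoupled solutions
#'
#' Argmax times of the uncoupled velocities (the uncoupled steady-state
#' timescales) and the corresponding steady levels
#' `(P_C, V_C, S_C)`, `(Q_C, U_C, I_C)`.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @return A one-row tibble.
#' @export
uncoupled_steady <- function(p) {
  k <- .uncoupled_const(p)
  tau_CS <- log(k$l2S / k$l1S) / (k$l2S - k$l1S)
  tau_CI <- log(k$l2I / k$l1I) / (k$l2I - k$l1I)
  st <- uncoupled_solutions(p, tau = c(tau_CS, tau_CI))
  tibble::tibble(tau_CS = tau_CS, tau_CI = tau_CI,
                 P_C = st$P[1], V_C = st$V[1], S_C = st$S[1],
                 Q_C = st$Q[2], U_C = st$U[2], I_C = st$I[2])
}

#' Steady-state timescales
#'
#' Collects every closed-form timescale of the fully competitive scheme:
#' the coupled estimates `tau_CS = alpha_I eta_S/(alpha_S alpha_I - 1)`,
#' `tau_CI = alpha_S eta_I/(alpha_S alpha_I - 1)`; the uncoupled argmax
#' times; the four biexponential timescales `tau_S1, tau_S2, tau_I1,
#' tau_I2` with separation ratios `delta_tau_S, delta_tau_I`; and the
#' matching ratio `psi = alpha_I eta_S/(alpha_S eta_I)` (`psi = 1` is the
#' common-steady-state condition). When the scale references are available
#' (parameter set produced by [nondimensionalize()]), dimensional `t_CS,
#' t_CI` in seconds are included via `t = tau / k2`.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @return A one-row tibble.
#' @export
timescales <- function(p) {
  dr <- .dr(p)
  den <- dr$alpha_S * dr$alpha_I - 1
  out <- tibble::tibble(
    tau_CS = dr$alpha_I * p$eta_S / den,
    tau_CI = dr$alpha_S * p$eta_I / den,
    psi = dr$psi)
  k <- tryCatch(.biexp_const(p), error = function(e) NULL)
  if (!is.null(k)) {
    out$tau_S1 <- 1 / k$l2S; out$tau_S2 <- 1 / k$l1S
    out$tau_I1 <- 1 / k$l2I; out$tau_I2 <- 1 / k$l1I
    out$delta_tau_S <- out$tau_S1 / out$tau_S2
    out$delta_tau_I <- out$tau_I1 / out$tau_I2
    out$tau_V_max <- log(k$l2S / k$l1S) / (k$l2S - k$l1S)
    out$tau_U_max <- log(k$l2I / k$l1I) / (k$l2I - k$l1I)
  }
  un <- tryCatch(uncoupled_steady(p), error = function(e) NULL)
  if (!is.null(un)) {
    out$tau_CS_uncoupled <- un$tau_CS
    out$tau_CI_uncoupled <- un$tau_CI
  }
  sc <- attr(p, "scales")
  if (!is.null(sc)) {
    out$t_CS <- out$tau_CS / sc[["k2"]]
    out$t_CI <- out$tau_CI / sc[["k2"]]
  }
  out
}

#' Timescales of the partial scheme
#'
#' `tau_CS = eta_S beta_I/(alpha_S beta_I - 1)` (substrate channel),
#' `tau_CY = 2 chi_I / sqrt(beta_I^2 - 4 eps_I)` (EI relaxation), the
#' matching ratio `xi = eta_S beta_I^2/(2 chi_I (alpha_S beta_I - 1))`, and
#' the two `beta_I` roots of the minimal-error condition `xi = 1`.
#'
#' @param pp A `ciket_partial_dimless` object.
#' @return A one-row tibble.
#' @export
timescales_partial <- function(pp) {
  g <- .drp(pp)
  den <- g$alpha_S * g$beta_I - 1
  disc <- g$alpha_S^2 * pp$chi_I^2 - 2 * pp$chi_I * pp$eta_S
  tibble::tibble(
    tau_CS = pp$eta_S * g$beta_I / den,
    tau_CY = 2 * pp$chi_I / sqrt(g$beta_I^2 - 4 * pp$eps_I),
    xi = pp$eta_S * g$beta_I^2 / (2 * pp$chi_I * den),
    beta_I_root_lo = if (disc >= 0)
      (g$alpha_S * pp$chi_I - sqrt(disc)) / pp$eta_S else NA_real_,
    beta_I_root_hi = if (disc >= 0)
      (g$alpha_S * pp$chi_I + sqrt(disc)) / pp$eta_S else NA_real_)
}

#' Reactant depletion time courses via Lambert W
#'
#' Closed inversions of the implicit post-steady depletion integral in
#' three delta regimes (each channel's integral is
#' `x + A ln x = 1 - rate * tau` for an effective Michaelis group `A`):
#' * `delta -> 0`: `S = mu_S_t W(exp((1 - eps_S tau)/mu_S_t)/mu_S_t)`,
#'   `I` with `A_I = mu_I_t (1 + mu_S_t)/mu_S_t` and rate `rho eps_I`;
#' * `delta -> 1`: shared form with `A = mu_S_t mu_I_t/(mu_S_t + mu_I_t)`;
#' * `delta -> Inf`: mirror of the first regime.
#' The regime is auto-selected from delta (`< 0.2`, `[0.2, 5]`, `> 5`); a
#' mismatch between the requested regime and delta is recorded as an
#' attribute `"regime_warning"`, not an error.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param tau Times (vectorized).
#' @param regime `"auto"`, `"delta0"`, `"delta1"` or `"deltaInf"`.
#' @return A tibble `tau, S, I` with attribute `"regime"`.
#' @export
depletion_time_courses <- function(p, tau,
                                   regime = c("auto", "delta0", "delta1",
                                              "deltaInf")) {
  regime <- match.arg(regime)
  dr <- .dr(p)
  band <- if (dr$delta < 0.2) "delta0" else if (dr$delta <= 5) "delta1"
  else "deltaInf"
  warned <- NULL
  if (regime == "auto") regime <- band
  else if (regime != band) {
    warned <- sprintf("regime %s requested but delta = %.4g suggests %s",
                      regime, dr$delta, band)
  }
  mS <- dr$mu_S_t; mI <- dr$mu_I_t
  if (regime == "delta0") {
    S <- mS * lambert_w0(exp((1 - p$eps_S * tau) / mS) / mS)
    AI <- mI * (mS + 1) / mS
    I <- AI * lambert_w0(exp((1 - p$rho * p$eps_I * tau) / AI) / AI)
  } else if (regime == "delta1") {
    A <- mS * mI / (mS + mI)
    kk <- 1 / A
    S <- A * lambert_w0(kk * exp(kk - p$eps_S * tau / mS))
    I <- A * lambert_w0(kk * exp(kk - p$rho * p$eps_I * tau / mI))
  } else {
    AS <- mS * (1 + mI) / mI
    S <- AS * lambert_w0(exp((1 - p$eps_S * tau) / AS) / AS)
    # delta -> Inf keeps I near 1 early; first-order 1/delta correction
    I <- mI * lambert_w0(exp((1 + mI / (dr$delta * mS) -
                                p$rho * p$eps_I * tau) / mI) / mI)
  }
  out <- tibble::tibble(tau = tau, S = S, I = I)
  attr(out, "regime") <- regime
  attr(out, "regime_warning") <- warned
  out
}

#' Residual of the implicit depletion integral
#'
#' Evaluates the substrate-channel implicit relation
#' `delta mu_S_t S^(1/delta) + mu_S_t mu_I_t ln S + mu_I_t S - mu_I_t -
#' delta mu_S_t + eps_S mu_I_t tau` at given `(tau, S)`; zero for exact
#' solutions.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param tau,S Matching vectors.
#' @return Numeric residuals.
#' @export
depletion_implicit_residual <- function(p, tau, S) {
  dr <- .dr(p)
  mS <- dr$mu_S_t; mI <- dr$mu_I_t; d <- dr$delta
  d * mS * S^(1 / d) + mS * mI * log(S) + mI * S - mI - d * mS +
    p$eps_S * mI * tau
}

# ---- partial-scheme transients ---------------------------------------

# internal: partial pre-steady constants
.pre_const_partial <- function(pp) {
  g <- .drp(pp)
  list(a = (g$alpha_S * g$beta_I - 1) / (pp$eta_S * g$beta_I),
       b = (g$beta_I - 1) / (pp$eta_S^3 * g$beta_I),
       V3 = pp$eps_S * (g$beta_I - 1) / (g$alpha_S * g$beta_I - 1),
       beta_I = g$beta_I)
}

#' EI-complex relaxation of the partial scheme
#'
#' For `eta_S -> 0` the EI complex obeys the Riccati equation
#' `chi_I dY/dtau = eps_I Y^2 - beta_I Y + 1`, solved exactly by
#' `Y = (beta_I - a coth(a tau/(2 chi_I) + artanh(a/beta_I)))/(2 eps_I)`
#' with `a = sqrt(beta_I^2 - 4 eps_I)`: `Y(0) = 0` and
#' `Y(Inf) = Y_inf` of [partial_equilibrium()].
#'
#' @param pp A `ciket_partial_dimless` object.
#' @param tau Times (vectorized).
#' @return A tibble `tau, Y, I`.
#' @export
partial_Y_tau <- function(pp, tau) {
  bI <- pp$beta_I
  a <- sqrt(bI^2 - 4 * pp$eps_I)
  Y <- (bI - a / tanh(a * tau / (2 * pp$chi_I) + atanh(a / bI))) /
    (2 * pp$eps_I)
  tibble::tibble(tau = tau, Y = Y, I = 1 - pp$eps_I * Y)
}

#' Pre-steady-state velocity of the partial scheme
#'
#' Same Lambert-W family as [presteady_V()] with `beta_I` replacing
#' `alpha_I`: plateau
#' `V3 = eps_S (beta_I - 1)/(alpha_S beta_I - 1)`, time form
#' `V = V3 (1 - exp(-tau/tau_CS))`, product form via `W(-exp(-1 - ...))`,
#' substrate form via `W((a-1) exp(a-1 + ...))` with
#' `a = (alpha_S beta_I - 1)/(eta_S beta_I)`,
#' `b = (beta_I - 1)/(eta_S^3 beta_I)`.
#'
#' @param pp A `ciket_partial_dimless` object.
#' @param tau,P,S Supply exactly one (vectorized).
#' @return A tibble with the coordinate and `V`.
#' @export
partial_presteady_V <- function(pp, tau = NULL, P = NULL, S = NULL) {
  k <- .pre_const_partial(pp)
  given <- sum(!is.null(tau), !is.null(P), !is.null(S))
  if (given != 1) stop("supply exactly one of tau, P, S", call. = FALSE)
  if (!is.null(tau)) {
    tibble::tibble(tau = tau, V = k$V3 * (1 - exp(-k$a * tau)))
  } else if (!is.null(P)) {
    arg <- -exp(-1 - k$a^2 * P / (k$b * pp$eps_S * pp$eta_S^2))
    tibble::tibble(P = P, V = k$V3 * (1 + lambert_w0(arg)))
  } else {
    R <- k$a - 1
    w <- .lambert_w0_exp(log(R) + R +
                           k$a^2 * (S - 1) / (k$b * pp$eps_S * pp$eta_S^2))
    tibble::tibble(S = S, V = k$V3 * (1 - w / R))
  }
}

#' Pre-steady EI complex against substrate (partial scheme)
#'
#' Numerically matched pre-steady form
#' `Y(S) = ((beta_I - 1)/(beta_I (alpha_S beta_I - 1))) *
#' (1 - W((a-1) exp(a-1 + a^2 (S-1)/(b eps_S eta_S^2)))/(a-1))`, whose
#' expansion near `S = 1` is `Y = (1 - S)/(eps_S beta_I) + O((S-1)^2)`;
#' `I` follows from `I = 1 - eps_I Y`.
#'
#' @param pp A `ciket_partial_dimless` object.
#' @param S Substrate levels (vectorized).
#' @return A tibble `S, Y, I`.
#' @export
partial_Y_S <- function(pp, S) {
  k <- .pre_const_partial(pp)
  R <- k$a - 1
  w <- .lambert_w0_exp(log(R) + R +
                         k$a^2 * (S - 1) / (k$b * pp$eps_S * pp$eta_S^2))
  Y <- (k$beta_I - 1) / (k$beta_I * (k$a * pp$eta_S * k$beta_I)) *
    (1 - w / R)
  # a * eta_S * beta_I = alpha_S beta_I - 1
  tibble::tibble(S = S, Y = Y, I = 1 - pp$eps_I * Y)
}

#' Biexponential velocity of the partial scheme
#'
#' Refined `(eps_I, chi_I, phi_S) -> 0` form: difference of exponentials
#' with `a = (alpha_S beta_I - 1)/(eta_S beta_I)`, `b = eps_S/eta_S`,
#' `c = (beta_I - 1)/(eta_S^3 beta_I)`.
#'
#' @param pp A `ciket_partial_dimless` object (overdamped regime).
#' @param tau Times (vectorized).
#' @return A tibble `tau, V, P`.
#' @export
biexponential_partial <- function(pp, tau) {
  k <- .pre_const_partial(pp)
  b <- pp$eps_S / pp$eta_S
  if (k$a^2 <= 4 * b) stop("complex-exponent regime", call. = FALSE)
  D <- sqrt(k$a^2 - 4 * b)
  l1 <- (k$a - D) / 2; l2 <- (k$a + D) / 2
  A <- k$b * pp$eps_S * pp$eta_S^2 / D
  tibble::tibble(tau = tau,
                 V = A * (exp(-l1 * tau) - exp(-l2 * tau)),
                 P = A * ((1 - exp(-l1 * tau)) / l1 -
                            (1 - exp(-l2 * tau)) / l2))
}
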