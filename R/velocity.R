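# Closed-form steady-state and post-steady-state velocity expressions for
# both schemes. All velocities are dimensionless: V = eps_S X in [0, eps_S],
# U = rho eps_I Y in [0, rho eps_I].

#' Classical sQSSA velocities
#'
#' The textbook quasi-steady-state pair obtained for
#' `(eta_S, eta_I) -> (0,0)`:
#' `V = eps_S S / (S + mu_S (1 + I/mu_I))`,
#' `U = rho eps_I I / (I + mu_I (1 + S/mu_S))`.
#' With `stationary = TRUE` the reactants are frozen at their totals
#' (`S = I = 1`), giving the velocities `V1, U1` used for reciprocal-plot
#' parameter estimation.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param S,I Reactant levels in `[0, 1]` (vectorized).
#' @param stationary If `TRUE`, evaluate at `S = I = 1`.
#' @return A tibble with columns `S, I, V, U` and a `space` tag.
#' @export
sqssa_velocity <- function(p, S = 1, I = 1, stationary = FALSE) {
  dr <- .dr(p)
  if (stationary) { S <- 1; I <- 1 }
  stopifnot(all(S >= 0 & S <= 1), all(I >= 0 & I <= 1))
  V <- p$eps_S * S / (S + dr$mu_S * (1 + I / dr$mu_I))
  U <- p$rho * p$eps_I * I / (I + dr$mu_I * (1 + S / dr$mu_S))
  tibble::tibble(S = S, I = I, V = V, U = U, space = "sqssa")
}

#' Refined sQSSA velocities
#'
#' Same structure as [sqssa_velocity()] but with the enzyme-corrected
#' Michaelis groups `mu_t = eps + mu` in place of `mu`, the refinement that
#' remains accurate at enzyme excess. In the product space the pair reads
#' `V = eps_S (1-P) / ((1-P) + mu_S_t (1 + (1-Q)/mu_I_t))` (and mirrored for
#' U). With `stationary = TRUE` the pair reduces to the plateau velocities
#' `V2 = eps_S (alpha_I - 1) / (alpha_S alpha_I - 1)` and
#' `U2 = rho eps_I (alpha_S - 1) / (alpha_S alpha_I - 1)`.
#'
#' @inheritParams sqssa_velocity
#' @param P,Q Product levels; when supplied, evaluation is in the `(P, Q)`
#'   space via `S = 1-P`, `I = 1-Q`.
#' @return A tibble with `S, I, V, U, space`.
#' @export
refined_sqssa_velocity <- function(p, S = NULL, I = NULL, P = NULL, Q = NULL,
                                   stationary = FALSE) {
  dr <- .dr(p)
  space <- "refined(S,I)"
  if (stationary) {
    S <- 1; I <- 1; space <- "refined-stationary"
  } else if (!is.null(P) || !is.null(Q)) {
    stopifnot(!is.null(P), !is.null(Q))
    S <- 1 - P; I <- 1 - Q; space <- "refined(P,Q)"
  }
  stopifnot(!is.null(S), !is.null(I))
  stopifnot(all(S >= 0 & S <= 1), all(I >= 0 & I <= 1))
  V <- p$eps_S * S / (S + dr$mu_S_t * (1 + I / dr$mu_I_t))
  U <- p$rho * p$eps_I * I / (I + dr$mu_I_t * (1 + S / dr$mu_S_t))
  tibble::tibble(S = S, I = I, V = V, U = U, space = space)
}

#' Post-steady coupling between the two reaction channels
#'
#' In the post-steady regime with `(eta_S, eta_I, eps_S, eps_I) -> 0` the
#' reactant and product pairs are tied by the acceleration-factor ratio:
#' `S = I^delta`, `I = S^(1/delta)`, `P = 1 - (1-Q)^delta`,
#' `Q = 1 - (1-P)^(1/delta)`.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param S,I,P,Q Exactly one of these, in `[0, 1]` (vectorized).
#' @return A tibble with all four coupled coordinates.
#' @export
coupling_curves <- function(p, S = NULL, I = NULL, P = NULL, Q = NULL) {
  delta <- .dr(p)$delta
  given <- c(S = !is.null(S), I = !is.null(I), P = !is.null(P),
             Q = !is.null(Q))
  if (sum(given) != 1) stop("supply exactly one of S, I, P, Q",
                            call. = FALSE)
  if (!is.null(S)) { I <- S^(1 / delta) }
  if (!is.null(I)) { S <- I^delta }
  if (!is.null(P)) { Q <- 1 - (1 - P)^(1 / delta); S <- 1 - P; I <- 1 - Q }
  if (!is.null(Q)) { P <- 1 - (1 - Q)^delta; S <- 1 - P; I <- 1 - Q }
  if (is.null(P)) { P <- 1 - S; Q <- 1 - I }
  x <- c(S, I, P, Q)
  stopifnot(all(x >= 0 & x <= 1))
  tibble::tibble(S = S, I = I, P = P, Q = Q, delta = delta)
}

# internal: polish a polynomial root by Newton iterations
.polish_root <- function(coefs, x, n = 3) {
  dcoefs <- coefs[-1] * seq_along(coefs[-1])
  for (i in seq_len(n)) {
    f <- sum(coefs * x^(seq_along(coefs) - 1))
    fp <- sum(dcoefs * x^(seq_along(dcoefs) - 1))
    if (fp == 0) break
    x <- x - f / fp
  }
  x
}

# internal: real roots of a polynomial given coefficients c0 + c1 x + ...
.real_roots <- function(coefs) {
  r <- polyroot(coefs)
  sc <- max(abs(r), 1)
  re <- Re(r[abs(Im(r)) < 1e-8 * sc])
  vapply(re, function(x) .polish_root(coefs, x), 0)
}

#' Cubic quasi-steady velocity pair in the product space
#'
#' For `(eta_S, eta_I) -> (0, 0)` the steady conditions in the `(V, P, Q)`
#' and `(U, P, Q)` spaces reduce to a pair of coupled quadrics whose
#' elimination yields a cubic in the EI-complex fraction Y; the physical
#' real root gives `U = rho eps_I Y` and V follows from the linear
#' back-substitution. Root selection: real roots filtered to the physical
#' box (complex fractions and free enzyme in `[0, 1]`, velocities in range);
#' among survivors the one nearest the refined-sQSSA pair is taken (small-eps
#' continuity).
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param P,Q Product levels in `[0, 1]` (scalars).
#' @return A one-row tibble with `V, U, X, Y, residual` (cubic residual at
#'   the returned root).
#' @export
cubic_qssa_vpq <- function(p, P, Q) {
  stopifnot(P >= 0, P <= 1, Q >= 0, Q <= 1)
  dr <- .dr(p)
  aS <- dr$alpha_S; aI <- dr$alpha_I
  eS <- p$eps_S; eI <- p$eps_I
  a3 <- eI * (aI * eS - aS * eI + eI - eS)
  a2 <- -P * aI * eI + P * eI^2 + P * eI + Q * aI * eS - 2 * Q * aS * eI +
    Q * eI * eS + 2 * Q * eI - Q * eS - aI^2 * eS + aI * aS * eI +
    aI * eS + aS * eI - eI^2 - eI * eS - 2 * eI
  a1 <- -(Q - 1) * (P * aI - P * eI - P + Q * aS - Q * eS - Q - aI * aS +
                      2 * aI * eS - aS * eI + 2 * eI - eS + 1)
  a0 <- (Q - 1)^2 * (aS - eS - 1)
  coefs <- c(a0, a1, a2, a3)
  Ys <- .real_roots(coefs)
  cand <- purrr::keep(Ys, function(Y) {
    den <- 1 - eI * Y - Q
    if (abs(den) < 1e-14) return(FALSE)
    X <- ((eI * Y + Q) * Y - aI * Y - Q + 1) / den
    Y >= -1e-10 && Y <= 1 + 1e-10 && X >= -1e-10 && X <= 1 + 1e-10 &&
      (1 - X - Y) >= -1e-10 && (1 - X - Y) <= 1 + 1e-10
  })
  if (!length(cand)) {
    stop("no real cubic root in the physical range at this (P, Q)",
         call. = FALSE)
  }
  ref <- refined_sqssa_velocity(p, P = P, Q = Q)
  score <- vapply(cand, function(Y) {
    X <- ((eI * Y + Q) * Y - aI * Y - Q + 1) / (1 - eI * Y - Q)
    sqrt((eS * X - ref$V)^2 + (p$rho * eI * Y - ref$U)^2)
  }, 0)
  Y <- cand[which.min(score)]
  X <- ((eI * Y + Q) * Y - aI * Y - Q + 1) / (1 - eI * Y - Q)
  tibble::tibble(V = eS * X, U = p$rho * eI * Y, X = X, Y = Y,
                 residual = abs(sum(coefs * Y^(0:3))))
}

#' Post-steady velocities with one product channel still closed
#'
#' The intermediate regime `(eta_S, eta_I, Q) -> (0,0,0)` (substrate
#' channel, valid for `eps_I -> 0`) closes the steady conditions into a
#' quadratic for the EI-complex fraction, giving the post-steady `V(S)`
#' branch; the mirrored regime `(eta_S, eta_I, P) -> (0,0,0)` gives `U(I)`.
#' These are the branches that track the simulated post-steady trajectories
#' accurately when delta is far from 1.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param S,I Supply exactly one: substrate level for the `V(S)` branch or
#'   inhibitor level for the `U(I)` branch (vectorized).
#' @return A tibble with the branch components (`V, P` or `U, Q`) plus the
#'   complex fractions.
#' @export
caseII_post_velocity <- function(p, S = NULL, I = NULL) {
  dr <- .dr(p)
  if (is.null(S) == is.null(I)) stop("supply exactly one of S or I",
                                     call. = FALSE)
  clip <- function(x) {
    if (any(x < -1e-12)) stop("negative radicand: parameter regime violated",
                              call. = FALSE)
    pmax(x, 0)
  }
  if (!is.null(S)) {
    stopifnot(all(S >= 0 & S <= 1))
    # here the quadratic variable is the ES-complex fraction
    A <- p$eps_I * dr$mu_S * (S + dr$mu_S)
    B <- S * (S * dr$mu_I + dr$alpha_I * dr$mu_S - 2 * p$eps_I * dr$mu_S)
    C <- -S^2 * dr$mu_I
    X <- (-B + sqrt(clip(B^2 - 4 * A * C))) / (2 * A)
    Y <- 1 - X * (S + dr$mu_S) / pmax(S, .Machine$double.eps)
    V <- p$eps_S * X
    tibble::tibble(S = S, V = V, P = 1 - V - S, X = X, Y = Y,
                   space = "caseII(V,S)")
  } else {
    stopifnot(all(I >= 0 & I <= 1))
    A <- p$eps_S * dr$mu_I * (I + dr$mu_I)
    B <- I * (I * dr$mu_S + dr$alpha_S * dr$mu_I - 2 * p$eps_S * dr$mu_I)
    C <- -I^2 * dr$mu_S
    Yei <- (-B + sqrt(clip(B^2 - 4 * A * C))) / (2 * A)
    # here the quadratic variable is the EI-complex fraction
    X <- (I - Yei * (I + dr$mu_I)) / pmax(I, .Machine$double.eps)
    U <- p$rho * p$eps_I * Yei
    tibble::tibble(I = I, U = U, Q = 1 - U / p$rho - I, X = X, Y = Yei,
                   space = "caseII(U,I)")
  }
}

#' First-order expansion of the post-steady velocities around delta = 1
#'
#' Expands the delta-coupled post-steady velocities in `(delta - 1)`:
#' `V(S) = V_ref(S) + (delta-1) eps_S mu_S_t S^2 ln S / (mu_I_t D_S^2)` with
#' `D_S = S + mu_S_t (1 + S/mu_I_t)` (and the mirrored, negative-signed term
#' for U). At `delta = 1` the expansion equals the refined sQSSA exactly and
#' the correction vanishes at `S = 1`.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param S,I Supply exactly one (vectorized, in `(0, 1]`).
#' @return A tibble with the expanded velocity and the zeroth-order term.
#' @export
taylor_delta_velocity <- function(p, S = NULL, I = NULL) {
  dr <- .dr(p)
  if (is.null(S) == is.null(I)) stop("supply exactly one of S or I",
                                     call. = FALSE)
  d1 <- dr$delta - 1
  if (!is.null(S)) {
    stopifnot(all(S > 0 & S <= 1))
    D <- S + dr$mu_S_t * (1 + S / dr$mu_I_t)
    V0 <- p$eps_S * S / D
    V <- V0 + d1 * p$eps_S * dr$mu_S_t * S^2 * log(S) / (dr$mu_I_t * D^2)
    tibble::tibble(S = S, V = V, V0 = V0)
  } else {
    stopifnot(all(I > 0 & I <= 1))
    D <- I + dr$mu_I_t * (1 + I / dr$mu_S_t)
    U0 <- p$rho * p$eps_I * I / D
    U <- U0 - d1 * p$rho * p$eps_I * dr$mu_I_t * I^2 * log(I) /
      (dr$mu_S_t * D^2)
    tibble::tibble(I = I, U = U, U0 = U0)
  }
}

#' Exact steady-state relations at the per-channel events
#'
#' At the substrate-channel steady state the exact velocity factorizes into
#' a Michaelis-Menten term and a modifying factor from the competing
#' channel: `V_CP = eps_S S_CP/(S_CP + mu_S) * (1 - U_CP/(rho eps_I))`;
#' mirrored, `U_CQ = rho eps_I I_CQ/(I_CQ + mu_I) * (1 - V_CQ/eps_S)`.
#' The cross-channel values are typically read off a simulated trajectory at
#' the detected event time.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param S_CP,U_CP Substrate level and cross-channel velocity at the
#'   X-event (for `V_CP`).
#' @param I_CQ,V_CQ Inhibitor level and cross-channel velocity at the
#'   Y-event (for `U_CQ`).
#' @return A one-row tibble with `V_CP` and/or `U_CQ`.
#' @export
exact_steady_relations <- function(p, S_CP = NULL, U_CP = NULL,
                                   I_CQ = NULL, V_CQ = NULL) {
  dr <- .dr(p)
  V_CP <- if (!is.null(S_CP)) {
    stopifnot(!is.null(U_CP))
    p$eps_S * S_CP / (S_CP + dr$mu_S) * (1 - U_CP / (p$rho * p$eps_I))
  } else NA_real_
  U_CQ <- if (!is.null(I_CQ)) {
    stopifnot(!is.null(V_CQ))
    p$rho * p$eps_I * I_CQ / (I_CQ + dr$mu_I) * (1 - V_CQ / p$eps_S)
  } else NA_real_
  tibble::tibble(V_CP = V_CP, U_CQ = U_CQ)
}

#' Prolonged secondary steady state
#'
#' When `delta < 1` the ES complex reaches its full-fledged steady state
#' only after the EI complex has been depleted; the prolonged substrate
#' level follows from `dV/dS = 0` on the delta-coupled velocity:
#' `S_C = (delta mu_I_t / (1 - delta))^delta`. For `delta > 1` the mirror
#' holds for the inhibitor: `I_C = (mu_S_t / (delta - 1))^(1/delta)`.
#' Product levels follow from the conservation planes. The branch is marked
#' invalid when the formula leaves `[0, 1]`.
#'
#' @param p A closed `ciket_full_dimless` object with `delta != 1`.
#' @return A one-row tibble: `channel`, `level` (S_C or I_C), `velocity`
#'   (V_C or U_C), `product` (P_C or Q_C), `valid`.
#' @export
secondary_steady_state <- function(p) {
  dr <- .dr(p)
  if (dr$delta == 1) stop("delta = 1: no secondary steady state",
                          call. = FALSE)
  if (dr$delta < 1) {
    S_C <- (dr$delta * dr$mu_I_t / (1 - dr$delta))^dr$delta
    if (S_C > 1 || !is.finite(S_C)) {
      return(tibble::tibble(channel = "substrate", level = NA_real_,
                            velocity = NA_real_, product = NA_real_,
                            valid = FALSE))
    }
    V_C <- p$eps_S * S_C /
      (S_C + dr$mu_S_t * (1 + S_C^(1 / dr$delta) / dr$mu_I_t))
    tibble::tibble(channel = "substrate", level = S_C, velocity = V_C,
                   product = 1 - S_C - V_C, valid = TRUE)
  } else {
    I_C <- (dr$mu_S_t / (dr$delta - 1))^(1 / dr$delta)
    if (I_C > 1 || !is.finite(I_C)) {
      return(tibble::tibble(channel = "inhibitor", level = NA_real_,
                            velocity = NA_real_, product = NA_real_,
                            valid = FALSE))
    }
    U_C <- p$rho * p$eps_I * I_C /
      (I_C + dr$mu_I_t * (1 + I_C^dr$delta / dr$mu_S_t))
    tibble::tibble(channel = "inhibitor", level = I_C, velocity = U_C,
                   product = 1 - I_C - U_C / p$rho, valid = TRUE)
  }
}

#' Total QSSA velocity pair
#'
#' The total-substrate QSSA closes the pre-steady balance
#' `(1 - eps_S X)(1 - X - Y) = mu_S X`,
#' `(1 - eps_I Y)(1 - X - Y) = mu_I Y` into a cubic
#' `a R^3 + b R^2 + c R - mu_S = 0` in `R = Y`. The closed cubic-root
#' expression is evaluated in complex arithmetic; if its real limit
#' disagrees with the polished numeric root by more than `1e-8` the numeric
#' root is used. tQSSA remains accurate at enzyme excess, where the
#' classical sQSSA breaks down.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @return A one-row tibble with `V, U, X, Y = R, residual`.
#' @export
tqssa_velocity <- function(p) {
  dr <- .dr(p)
  eS <- p$eps_S; eI <- p$eps_I; mS <- dr$mu_S; mI <- dr$mu_I
  a <- eI^2 * mS - eI * eS * mI
  b <- -eI^2 * mS + eI * eS * mI - eI * mI * mS - eI * mI - 2 * eI * mS +
    eS * mI^2 + eS * mI
  cc <- 2 * eI * mS - eS * mI + mI * mS + mI + mS
  coefs <- c(-mS, cc, b, a)
  phys <- function(Y) {
    X <- 1 - Y - mI * Y / (1 - eI * Y)
    is.finite(X) && eI * Y >= -1e-10 && eI * Y <= 1 + 1e-10 &&
      Y >= -1e-10 && X >= -1e-10 && X <= 1 + 1e-10 &&
      (1 - X - Y) >= -1e-10
  }
  Ys <- if (abs(a) > 1e-14) .real_roots(coefs) else
    .real_roots(coefs[1:3])
  cand <- purrr::keep(Ys, phys)
  if (!length(cand)) stop("no tQSSA root with 0 <= eps_I R <= 1",
                          call. = FALSE)
  Y_num <- if (length(cand) == 1) cand else {
    ref <- refined_sqssa_velocity(p, stationary = TRUE)
    score <- vapply(cand, function(Y) {
      X <- 1 - Y - mI * Y / (1 - eI * Y)
      sqrt((eS * X - ref$V)^2 + (p$rho * eI * Y - ref$U)^2)
    }, 0)
    cand[which.min(score)]
  }
  Y <- Y_num
  if (abs(a) > 1e-14) {
    # closed form evaluated in complex arithmetic, real limit taken
    Z <- 27 * a^2 * mS^2 + 18 * a * b * cc * mS + 4 * a * cc^3 -
      4 * b^3 * mS - b^2 * cc^2
    H <- 12 * sqrt(as.complex(3 * Z)) * a + 108 * mS * a^2 +
      36 * cc * b * a - 8 * b^3
    H3 <- H^(1 / 3)
    Rcf <- H3 / (6 * a) - 2 * (3 * a * cc - b^2) / (3 * a * H3) - b / (3 * a)
    if (abs(Im(Rcf)) < 1e-8 && abs(Re(Rcf) - Y_num) < 1e-8) Y <- Re(Rcf)
  }
  X <- 1 - Y - mI * Y / (1 - eI * Y)
  tibble::tibble(V = eS * X, U = p$rho * eI * Y, X = X, Y = Y,
                 residual = abs(sum(c(-mS, cc, b, a) * Y^(0:3))))
}

#' sQSSA velocities of the partial scheme
#'
#' Classical form (`(eta_S, chi_I) -> 0`):
#' `V = eps_S S / (S + mu_S (1 + I/kappa_I))`,
#' `Y = I / (I + kappa_I (1 + S/mu_S))`; the refined variant replaces
#' `mu_S -> mu_S_t`, `kappa_I -> kappa_I_t` with the inhibitor frozen at
#' `I = 1`. `stationary = TRUE` additionally sets `S = 1`.
#'
#' @param pp A `ciket_partial_dimless` object.
#' @param S,I Reactant levels in `[0, 1]` (I is ignored by the refined
#'   variant, which already assumes `I = 1`).
#' @param refined Use the enzyme-corrected groups.
#' @param stationary Freeze reactants at their totals.
#' @return A tibble with `S, V, Y` and a `space` tag.
#' @export
partial_sqssa <- function(pp, S = 1, I = 1, refined = FALSE,
                          stationary = FALSE) {
  stopifnot(inherits(pp, "ciket_partial_dimless"))
  g <- .drp(pp)
  if (stationary) { S <- 1; I <- 1 }
  stopifnot(all(S >= 0 & S <= 1), all(I >= 0 & I <= 1))
  if (refined) {
    V <- pp$eps_S * S / (S + g$mu_S_t * (1 + 1 / g$kappa_I_t))
    Y <- 1 / (1 + g$kappa_I_t * (1 + S / g$mu_S_t))
    tibble::tibble(S = S, V = V, Y = Y, space = "partial-refined")
  } else {
    V <- pp$eps_S * S / (S + g$mu_S * (1 + I / pp$kappa_I))
    Y <- I / (I + pp$kappa_I * (1 + S / g$mu_S))
    tibble::tibble(S = S, V = V, Y = Y, space = "partial-sqssa")
  }
}

#' Post-steady parametric set of the partial scheme
#'
#' For `(eta_S, chi_I) -> (0, 0)` the steady conditions close into a
#' quadratic for the EI-complex fraction; with
#' `h = sqrt((kappa_I S + mu_S beta_I)^2 - 4 eps_I mu_S^2)`,
#' `Y(S) = (kappa_I S + mu_S beta_I - h) / (2 eps_I mu_S)`,
#' `I = 1 - eps_I Y`, `V = eps_S S (1 - Y)/(S + mu_S)` and `P = 1 - V - S`.
#' At `S = 0` the set returns the exact binding equilibrium
#' `Y_inf = (beta_I - sqrt(beta_I^2 - 4 eps_I)) / (2 eps_I)`.
#'
#' @param pp A `ciket_partial_dimless` object.
#' @param S Substrate levels in `[0, 1]` (vectorized).
#' @return A tibble with `S, V, P, Y, I`.
#' @export
partial_post_vs <- function(pp, S) {
  stopifnot(inherits(pp, "ciket_partial_dimless"), all(S >= 0 & S <= 1))
  g <- .drp(pp)
  rad <- (pp$kappa_I * S + g$mu_S * g$beta_I)^2 - 4 * pp$eps_I * g$mu_S^2
  if (any(rad < -1e-12)) stop("negative radicand: regime violation",
                              call. = FALSE)
  h <- sqrt(pmax(rad, 0))
  Y <- (pp$kappa_I * S + g$mu_S * g$beta_I - h) / (2 * pp$eps_I * g$mu_S)
  V <- pp$eps_S * S * (1 - Y) / (S + g$mu_S)
  tibble::tibble(S = S, V = V, P = 1 - V - S, Y = Y, I = 1 - pp$eps_I * Y)
}

#' Terminal equilibrium of the partial scheme
#'
#' @param pp A `ciket_partial_dimless` object.
#' @return A one-row tibble with `Y_inf` and `I_inf`.
#' @export
partial_equilibrium <- function(pp) {
  stopifnot(inherits(pp, "ciket_partial_dimless"))
  bI <- pp$beta_I
  Y_inf <- (bI - sqrt(bI^2 - 4 * pp$eps_I)) / (2 * pp$eps_I)
  tibble::tibble(Y_inf = Y_inf, I_inf = 1 - pp$eps_I * Y_inf)
}
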