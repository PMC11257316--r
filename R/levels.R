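# Steady-state reactant levels from pre/post-steady-state intersections.
# The pre-steady trajectories hug the edges V = 1 - S (and U = rho (1 - I))
# of the phase triangle, so intersecting those lines with a post-steady
# branch approximates the steady level of the corresponding reactant.

# internal: largest root of f on (0, 1) by grid scan + uniroot
.largest_root01 <- function(f, n = 2000) {
  x <- seq(1e-9, 1 - 1e-9, length.out = n)
  fx <- vapply(x, f, 0)
  sgn <- sign(fx)
  idx <- which(sgn[-1] != sgn[-n] & sgn[-1] != 0)
  if (!length(idx)) stop("no root in (0, 1)", call. = FALSE)
  i <- idx[length(idx)]
  stats::uniroot(f, c(x[i], x[i + 1]), tol = 1e-14)$root
}

#' Steady-state levels of the fully competitive scheme
#'
#' Intersects the pre-steady edges `V = 1 - S` and `U = rho (1 - I)` with a
#' post-steady branch:
#' * `"power"` — the delta-coupled refined branch
#'   `eps_S S/(S + mu_S_t (1 + S^(1/delta)/mu_I_t)) = 1 - S` (and the
#'   mirrored inhibitor equation), solved by bracketed root-finding, taking
#'   the largest root below 1 (the branch reached first from the stationary
#'   start);
#' * `"closed"` — the explicit quadratic solutions available at `delta = 1`;
#' * `"refined"` — the one-channel-closed post branches of
#'   [caseII_post_velocity()] intersected with the same edges.
#' `"auto"` selects `"closed"` when `delta` is within `[0.99, 1.01]` and
#' `"power"` otherwise. Velocities at the intersection follow from the
#' delta-coupled velocity expressions.
#'
#' @param p A closed `ciket_full_dimless` object.
#' @param method One of `"auto"`, `"power"`, `"closed"`, `"refined"`.
#' @return A tibble with one row per channel: `channel, level, velocity,
#'   method, residual` (residual of the defining scalar equation).
#' @export
full_intersection_levels <- function(p, method = c("auto", "power", "closed",
                                                   "refined")) {
  method <- match.arg(method)
  dr <- .dr(p)
  if (method == "auto") {
    method <- if (abs(dr$delta - 1) <= 0.01) "closed" else "power"
  }
  mS <- dr$mu_S_t; mI <- dr$mu_I_t; d <- dr$delta
  vS <- function(S) p$eps_S * S / (S + mS * (1 + S^(1 / d) / mI))
  uI <- function(I) p$rho * p$eps_I * I / (I + mI * (1 + I^d / mS))
  if (method == "power") {
    S_C <- .largest_root01(function(S) vS(S) - (1 - S))
    I_C <- .largest_root01(function(I) uI(I) - p$rho * (1 - I))
    res_S <- abs(vS(S_C) - (1 - S_C))
    res_I <- abs(uI(I_C) - p$rho * (1 - I_C))
  } else if (method == "closed") {
    # delta = 1 quadratics: (mS+mI) x^2 + B x - mS mI = 0
    BS <- mS * mI + p$eps_S * mI - mI - mS
    S_C <- (-BS + sqrt(BS^2 + 4 * (mS + mI) * mS * mI)) / (2 * (mS + mI))
    BI <- mS * mI + p$eps_I * mS - mI - mS
    I_C <- (-BI + sqrt(BI^2 + 4 * (mS + mI) * mS * mI)) / (2 * (mS + mI))
    res_S <- abs(p$eps_S * S_C / (S_C + mS * (1 + S_C / mI)) - (1 - S_C))
    res_I <- abs(p$rho * p$eps_I * I_C / (I_C + mI * (1 + I_C / mS)) -
                   p$rho * (1 - I_C))
  } else {
    S_C <- .largest_root01(function(S)
      caseII_post_velocity(p, S = S)$V - (1 - S))
    I_C <- .largest_root01(function(I)
      caseII_post_velocity(p, I = I)$U - p$rho * (1 - I))
    res_S <- abs(caseII_post_velocity(p, S = S_C)$V - (1 - S_C))
    res_I <- abs(caseII_post_velocity(p, I = I_C)$U - p$rho * (1 - I_C))
  }
  tibble::tibble(
    channel = c("substrate", "inhibitor"),
    level = c(S_C, I_C),
    velocity = c(vS(S_C), uI(I_C)),
    method = method,
    residual = c(res_S, res_I))
}

#' Steady-state substrate level of the partial scheme
#'
#' * `"quadratic"` — intersects the refined sQSSA branch
#'   `eps_S S/(S + mu_S_t (1 + 1/kappa_I_t)) = 1 - S`, which closes into a
#'   quadratic with explicit root
#'   `S_C = (1 - m - eps_S + sqrt((m + eps_S - 1)^2 + 4 m))/2`,
#'   `m = mu_S_t (1 + 1/kappa_I_t)`. The reported velocity is the refined
#'   branch at `S_C`; `velocity_refined` re-evaluates it on the more
#'   accurate [partial_post_vs()] branch.
#' * `"cubic"` — intersects [partial_post_vs()] with `V = 1 - S` directly
#'   (the cubic-order equation), solved numerically.
#'
#' @param pp A `ciket_partial_dimless` object.
#' @param method `"quadratic"` or `"cubic"`.
#' @return A one-row tibble `level, velocity, velocity_refined, method,
#'   residual`.
#' @export
partial_intersection_levels <- function(pp, method = c("quadratic",
                                                       "cubic")) {
  method <- match.arg(method)
  g <- .drp(pp)
  m <- g$mu_S_t * (1 + 1 / g$kappa_I_t)
  if (method == "quadratic") {
    S_C <- (1 - m - pp$eps_S + sqrt((m + pp$eps_S - 1)^2 + 4 * m)) / 2
    V_C <- pp$eps_S * S_C / (S_C + m)
    residual <- abs(V_C - (1 - S_C))
  } else {
    S_C <- .largest_root01(function(S) partial_post_vs(pp, S)$V - (1 - S))
    V_C <- partial_post_vs(pp, S_C)$V
    residual <- abs(V_C - (1 - S_C))
  }
  tibble::tibble(level = S_C, velocity = V_C,
                 velocity_refined = partial_post_vs(pp, S_C)$V,
                 method = method, residual = residual)
}
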