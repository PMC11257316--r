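#' @useDynLib ciket, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# internal: output grid for the reference integrator -- a point at 0 plus a
# geometric grid resolving the fast boundary layer of width ~ eta/alpha.
.out_grid <- function(tau1, tau_end, n_out) {
  tau1 <- min(tau1, tau_end / 10)
  c(0, exp(seq(log(tau1), log(tau_end), length.out = n_out - 1)))
}

.new_trajectory <- function(df, scheme, params, method, dtau = NA_real_) {
  out <- tibble::as_tibble(df)
  class(out) <- c("ciket_trajectory", class(out))
  attr(out, "scheme") <- scheme
  attr(out, "params") <- params
  attr(out, "method") <- method
  attr(out, "dtau") <- dtau
  out
}

#' Simulate the fully competitive inhibition scheme
#'
#' Integrates the dimensionless rate equations
#' `eta_S dX/dtau = S(1-X-Y) - (eta_S+kappa_S) X`,
#' `(eta_I/rho) dY/dtau = I(1-X-Y) - (eta_I+kappa_I) Y`,
#' `dP/dtau = eps_S X`, `dQ/dtau = rho eps_I Y`
#' from the canonical initial state `(S,I,E,X,Y,P,Q) = (1,1,1,0,0,0,0)`.
#' The reactants S, I and the free enzyme E are co-integrated as redundant
#' states so that the conservation planes `V+P+S = 1` and `U/rho+Q+I = 1`
#' ([conservation_residuals()]) measure integration accuracy.
#'
#' @param p A closed `ciket_full_dimless` parameter set.
#' @param tau_end Integration horizon; defaults to `50/min(eps_S, rho eps_I)`
#'   (the slower product channel), truncated once both reactants fall below
#'   `1e-3`.
#' @param dtau Euler step (used by `method = "euler"`; must be `<= 1e-5` to
#'   resolve the fastest boundary layer).
#' @param method `"reference"` (adaptive lsoda, the accuracy oracle) or
#'   `"euler"` (the explicit scheme of the theory, fixed step).
#' @param n_out Number of stored grid points.
#' @return A `ciket_trajectory` tibble with columns
#'   `tau, S, I, E, X, Y, P, Q, V, U`.
#' @examples
#' p <- full_dimless(0.2, 4.1, 3.1, 0.1, 1.2, 0.1, rho = 10)
#' traj <- simulate_full(p)
#' detect_steady_states(traj)
#' @export
simulate_full <- function(p, tau_end = NULL, dtau = 1e-5,
                          method = c("reference", "euler"), n_out = 4000) {
  stopifnot(inherits(p, "ciket_full_dimless"))
  if (is.na(p$rho)) stop("rho must be set (see close_parameters())",
                         call. = FALSE)
  method <- match.arg(method)
  dr <- .dr(p)
  tau_end <- tau_end %||% (50 / min(p$eps_S, p$rho * p$eps_I))
  if (tau_end <= 0) stop("tau_end must be positive", call. = FALSE)
  if (method == "euler") {
    if (dtau > 1e-5) stop("euler requires dtau <= 1e-5", call. = FALSE)
    res <- euler_full_cpp(p$eta_S, p$eps_S, p$kappa_S, p$eta_I, p$eps_I,
                          p$kappa_I, p$rho, tau_end, dtau, 200000L, 1e-3)
    if (nzchar(res$bad)) {
      stop(sprintf("euler step unstable: state %s left [-0.01, 1.01]; %s",
                   res$bad, "reduce dtau"), call. = FALSE)
    }
    df <- tibble::tibble(tau = res$tau, S = res$S, I = res$I, E = res$E,
                         X = res$X, Y = res$Y, P = res$P, Q = res$Q)
  } else {
    rhs <- function(t, y, parms) {
      X <- y[1]; Y <- y[2]; P <- y[3]; Q <- y[4]
      Sc <- 1 - p$eps_S * X - P
      Ic <- 1 - p$eps_I * Y - Q
      dX <- (Sc * (1 - X - Y) - dr$mu_S * X) / p$eta_S
      dY <- p$rho * (Ic * (1 - X - Y) - dr$mu_I * Y) / p$eta_I
      dP <- p$eps_S * X
      dQ <- p$rho * p$eps_I * Y
      list(c(dX, dY, dP, dQ,
             -p$eps_S * dX - dP, -p$eps_I * dY - dQ, -(dX + dY)))
    }
    bl <- min(p$eta_S / dr$alpha_S, p$eta_I / (p$rho * dr$alpha_I))
    times <- .out_grid(bl / 50, tau_end, n_out)
    sol <- deSolve::lsoda(c(X = 0, Y = 0, P = 0, Q = 0, S = 1, I = 1, E = 1),
                          times, rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
    df <- tibble::as_tibble(as.data.frame(sol))
    names(df)[1] <- "tau"
    done <- which(df$S < 1e-3 & df$I < 1e-3)
    if (length(done) > 1) df <- df[seq_len(done[1]), ]
    df <- df[, c("tau", "S", "I", "E", "X", "Y", "P", "Q")]
    if (any(df$X < -0.01 | df$X > 1.01 | df$Y < -0.01 | df$Y > 1.01)) {
      stop("integration unstable: complex fraction left [-0.01, 1.01]",
           call. = FALSE)
    }
  }
  df$V <- p$eps_S * df$X
  df$U <- p$rho * p$eps_I * df$Y
  .new_trajectory(df, "full", p, method, if (method == "euler") dtau else NA)
}

#' Simulate the partial competitive inhibition scheme
#'
#' Integrates the dead-end complex scheme
#' `eta_S dX/dtau = (1 - eps_S X - P)(1-X-Y) - (eta_S+kappa_S) X`,
#' `chi_I dY/dtau = (1 - eps_I Y)(1-X-Y) - kappa_I Y`, `dP/dtau = eps_S X`.
#' The terminal state has the substrate exhausted (`S -> 0`, `P -> 1`) and
#' the EI complex at its binding equilibrium
#' `Y_inf = (beta_I - sqrt(beta_I^2 - 4 eps_I)) / (2 eps_I)`.
#'
#' @inheritParams simulate_full
#' @param pp A `ciket_partial_dimless` parameter set.
#' @return A `ciket_trajectory` tibble with columns
#'   `tau, S, I, E, X, Y, P, V`.
#' @export
simulate_partial <- function(pp, tau_end = NULL, dtau = 1e-5,
                             method = c("reference", "euler"),
                             n_out = 4000) {
  stopifnot(inherits(pp, "ciket_partial_dimless"))
  method <- match.arg(method)
  g <- .drp(pp)
  tau_end <- tau_end %||% (50 / pp$eps_S)
  if (method == "euler") {
    if (dtau > 1e-5) stop("euler requires dtau <= 1e-5", call. = FALSE)
    res <- euler_partial_cpp(pp$eta_S, pp$eps_S, pp$kappa_S, pp$chi_I,
                             pp$eps_I, pp$kappa_I, tau_end, dtau, 200000L,
                             1e-3)
    if (nzchar(res$bad)) {
      stop(sprintf("euler step unstable: state %s left [-0.01, 1.01]",
                   res$bad), call. = FALSE)
    }
    df <- tibble::tibble(tau = res$tau, S = res$S, I = res$I, E = res$E,
                         X = res$X, Y = res$Y, P = res$P)
  } else {
    rhs <- function(t, y, parms) {
      X <- y[1]; Y <- y[2]; P <- y[3]
      Sc <- 1 - pp$eps_S * X - P
      Ic <- 1 - pp$eps_I * Y
      dX <- (Sc * (1 - X - Y) - g$mu_S * X) / pp$eta_S
      dY <- (Ic * (1 - X - Y) - pp$kappa_I * Y) / pp$chi_I
      dP <- pp$eps_S * X
      list(c(dX, dY, dP, -pp$eps_S * dX - dP, -pp$eps_I * dY, -(dX + dY)))
    }
    bl <- min(pp$eta_S / g$alpha_S, pp$chi_I / g$beta_I)
    times <- .out_grid(bl / 50, tau_end, n_out)
    sol <- deSolve::lsoda(c(X = 0, Y = 0, P = 0, S = 1, I = 1, E = 1),
                          times, rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
    df <- tibble::as_tibble(as.data.frame(sol))
    names(df)[1] <- "tau"
    dY <- ((1 - pp$eps_I * df$Y) * (1 - df$X - df$Y) -
             pp$kappa_I * df$Y) / pp$chi_I
    done <- which(df$S < 1e-3 & abs(dY) < 1e-7)
    if (length(done) > 1) df <- df[seq_len(done[1]), ]
    df <- df[, c("tau", "S", "I", "E", "X", "Y", "P")]
  }
  df$V <- pp$eps_S * df$X
  .new_trajectory(df, "partial", pp, method,
                  if (method == "euler") dtau else NA)
}

#' Simulate the phi-approximation linear system
#'
#' When the nonlinearity weights `phi_S = eta_S eps_S` and
#' `phi_I = eta_I eps_I` vanish, the second-order form of the fully
#' competitive scheme becomes a coupled *linear* system in the rescaled
#' products `M = P/(eps_S eta_S^2)` and `N = Q/(eps_I eta_I^2)`. This
#' routine integrates that system and maps back through
#' `(P, V) = eps_S eta_S^2 (M, M')`, `(Q, U) = eps_I eta_I^2 (N, N')`, with
#' S and I recovered from the conservation planes. As
#' `(phi_S, phi_I) -> 0` the phi trajectory converges (first order in phi)
#' to the full simulation.
#'
#' @inheritParams simulate_full
#' @return A `ciket_trajectory` tibble (same columns as [simulate_full()]).
#' @seealso [phi_quartic_coeffs()] for the characteristic quartic of the
#'   system.
#' @export
simulate_phi <- function(p, tau_end = NULL, dtau = 1e-5,
                         method = c("reference", "euler"), n_out = 4000) {
  stopifnot(inherits(p, "ciket_full_dimless"))
  method <- match.arg(method)
  dr <- .dr(p)
  tau_end <- tau_end %||% (50 / min(p$eps_S, p$rho * p$eps_I))
  if (method == "euler") {
    if (dtau > 1e-5) stop("euler requires dtau <= 1e-5", call. = FALSE)
    res <- euler_phi_cpp(p$eta_S, p$eps_S, p$eta_I, p$eps_I, p$rho,
                         dr$alpha_S, dr$alpha_I, tau_end, dtau, 200000L)
    df0 <- tibble::tibble(tau = res$tau, M = res$M, F = res$F,
                          N = res$N, G = res$G)
  } else {
    A <- .phi_system_matrix(p)
    b <- c(0, 1 / p$eta_S^3, 0, p$rho^2 / p$eta_I^3)
    rhs <- function(t, y, parms) list(as.vector(A %*% y) + b)
    bl <- min(p$eta_S / dr$alpha_S, p$eta_I / (p$rho * dr$alpha_I))
    times <- .out_grid(bl / 50, tau_end, n_out)
    sol <- deSolve::lsoda(c(M = 0, F = 0, N = 0, G = 0), times, rhs,
                          parms = NULL, rtol = 1e-10, atol = 1e-12,
                          maxsteps = 50000)
    df0 <- tibble::as_tibble(as.data.frame(sol))
    names(df0)[1] <- "tau"
  }
  P <- p$eps_S * p$eta_S^2 * df0$M
  V <- p$eps_S * p$eta_S^2 * df0$F
  Q <- p$eps_I * p$eta_I^2 * df0$N
  U <- p$eps_I * p$eta_I^2 * df0$G
  df <- tibble::tibble(
    tau = df0$tau,
    S = 1 - V - P, I = 1 - U / p$rho - Q,
    E = 1 - V / p$eps_S - U / (p$rho * p$eps_I),
    X = V / p$eps_S, Y = U / (p$rho * p$eps_I),
    P = P, Q = Q, V = V, U = U)
  .new_trajectory(df, "phi", p, method, if (method == "euler") dtau else NA)
}

# internal: companion matrix of the phi linear system in (M, F, N, G)
.phi_system_matrix <- function(p) {
  dr <- .dr(p)
  matrix(c(
    0, 1, 0, 0,
    -p$eps_S / p$eta_S, -dr$alpha_S / p$eta_S, 0,
    -p$eta_I^2 / (p$rho * p$eta_S^3),
    0, 0, 0, 1,
    0, -p$rho^2 * p$eta_S^2 / p$eta_I^3,
    -p$eps_I * p$rho^2 / p$eta_I, -p$rho * dr$alpha_I / p$eta_I),
    nrow = 4, byrow = TRUE)
}

#' Characteristic quartic of the phi-approximation
#'
#' Coefficients `(a, b, c, h)` of the uncoupled fourth-order form
#' `M'''' + a M''' + b M'' + c M' + h M = const` (the `N`-space elimination
#' yields the same characteristic polynomial, as both carry the eigenvalues
#' of the coupled linear system).
#'
#' @param p A closed `ciket_full_dimless` object.
#' @return A one-row tibble with columns `a, b, c, h` and the four
#'   eigenvalue roots of the quartic as a list-column `roots`.
#' @export
phi_quartic_coeffs <- function(p) {
  dr <- .dr(p)
  a <- dr$alpha_S / p$eta_S + p$rho * dr$alpha_I / p$eta_I
  b <- p$eps_S / p$eta_S + p$rho * (dr$alpha_S * dr$alpha_I - 1) /
    (p$eta_S * p$eta_I) + p$eps_I * p$rho^2 / p$eta_I
  cc <- p$rho * (dr$alpha_I * p$eps_S + p$rho * p$eps_I * dr$alpha_S) /
    (p$eta_S * p$eta_I)
  h <- p$eps_S * p$eps_I * p$rho^2 / (p$eta_S * p$eta_I)
  roots <- polyroot(c(h, cc, b, a, 1))
  tibble::tibble(a = a, b = b, c = cc, h = h, roots = list(roots))
}

#' Detect steady-state events on a trajectory
#'
#' A steady state of a complex is a time `0 < tau_c < Inf` at which its time
#' derivative vanishes. Events are located as sign changes of the centered
#' finite-difference derivative of X (substrate channel) and Y (inhibitor
#' channel) on the stored grid, with a dead band against floating-point
#' chatter, a persistence requirement (derivative of one sign over at least
#' 3 consecutive points before the crossing), and exclusion of the trivial
#' terminal decay (complex below `floor` and monotonically decreasing).
#' The first maximum per channel is the transient *primary* steady state;
#' any later maximum is the prolonged *secondary* one (present when the
#' acceleration-factor ratio delta is far from 1).
#'
#' @param traj A `ciket_trajectory`.
#' @param deadband Absolute derivative dead band (default `1e-12`).
#' @param floor Terminal decay floor on the complex fraction (default
#'   `1e-4`).
#' @return A tibble with one row per extremum: `channel` ("substrate" or
#'   "inhibitor"), `type` ("maximum"/"minimum"), `order`
#'   ("primary"/"secondary" for maxima, NA for minima), `tau`, and the
#'   interpolated state columns at the event.
#' @export
detect_steady_states <- function(traj, deadband = 1e-12, floor = 1e-4) {
  stopifnot(inherits(traj, "ciket_trajectory"))
  if (nrow(traj) < 3) stop("trajectory must have at least 3 points",
                           call. = FALSE)
  scan <- function(var, channel) {
    x <- traj[[var]]
    tau <- traj$tau
    n <- length(x)
    d <- (x[3:n] - x[1:(n - 2)]) / (tau[3:n] - tau[1:(n - 2)])
    dt <- tau[2:(n - 1)]
    sgn <- sign(d) * (abs(d) > deadband)
    idx <- which(sgn[-length(sgn)] != sgn[-1] &
                   sgn[-length(sgn)] != 0 & sgn[-1] != 0)
    if (!length(idx)) return(NULL)
    rows <- purrr::map(idx, function(i) {
      before <- sgn[max(1, i - 2):i]
      if (length(before) < 3 || any(before != sgn[i])) return(NULL)
      # terminal decay / float noise: complex already negligible
      if (x[i + 1] < floor) return(NULL)
      # interpolate the derivative zero between grid points i and i+1
      w <- abs(d[i]) / (abs(d[i]) + abs(d[i + 1]))
      tau_c <- dt[i] + w * (dt[i + 1] - dt[i])
      st <- purrr::map_dbl(
        setdiff(names(traj), "tau"),
        function(v) {
          y <- traj[[v]]
          y[i + 1] + w * (y[i + 2] - y[i + 1])
        })
      names(st) <- setdiff(names(traj), "tau")
      tibble::tibble(channel = channel,
                     type = if (sgn[i] > 0) "maximum" else "minimum",
                     tau = tau_c, !!!as.list(st))
    })
    dplyr::bind_rows(rows)
  }
  ev <- dplyr::bind_rows(scan("X", "substrate"), scan("Y", "inhibitor"))
  if (!nrow(ev)) {
    return(tibble::tibble(channel = character(), type = character(),
                          order = character(), tau = double()))
  }
  ev <- dplyr::arrange(ev, .data$channel, .data$tau)
  ev <- dplyr::mutate(
    dplyr::group_by(ev, .data$channel),
    order = dplyr::if_else(
      .data$type == "maximum",
      dplyr::if_else(cumsum(.data$type == "maximum") == 1L,
                     "primary", "secondary"),
      NA_character_))
  dplyr::relocate(dplyr::ungroup(ev), "channel", "type", "order", "tau")
}

#' Conservation-plane residuals of a trajectory
#'
#' All exact trajectories of the fully competitive scheme lie on the planes
#' `V + P + S = 1` and `U/rho + Q + I = 1`, with `E = 1 - X - Y`; for the
#' partial scheme the inhibitor relation is `I = 1 - eps_I Y`. Because the
#' simulators co-integrate S, I and E as independent states, the maximal
#' absolute deviations from these planes measure integrator accuracy
#' (`< 1e-6` for the reference integrator, `< 1e-3` for Euler at
#' `dtau = 1e-5`).
#'
#' @param traj A `ciket_trajectory`.
#' @return A one-row tibble with `res_VPS`, `res_UQI` (NA for the partial
#'   scheme, replaced by the `I = 1 - eps_I Y` residual `res_I`), `res_E`.
#' @export
conservation_residuals <- function(traj) {
  stopifnot(inherits(traj, "ciket_trajectory"))
  p <- attr(traj, "params")
  scheme <- attr(traj, "scheme")
  res_VPS <- max(abs(traj$V + traj$P + traj$S - 1))
  res_E <- max(abs(traj$E - (1 - traj$X - traj$Y)))
  if (scheme == "partial") {
    tibble::tibble(res_VPS = res_VPS, res_UQI = NA_real_,
                   res_I = max(abs(traj$I - (1 - p$eps_I * traj$Y))),
                   res_E = res_E)
  } else {
    tibble::tibble(res_VPS = res_VPS,
                   res_UQI = max(abs(traj$U / p$rho + traj$Q + traj$I - 1)),
                   res_I = NA_real_, res_E = res_E)
  }
}
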