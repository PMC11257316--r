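# Synthetic steady-state velocity datasets and nonlinear least-squares
# parameter recovery for the dimensional velocity laws.

# internal: closed-form dimensional velocity laws v(s0, i0) and u(s0, i0)
.velocity_law <- function(model) {
  switch(model,
    sqssa = function(s0, i0, e0, vmax, KMS, KMI, umax = NA)
      vmax * s0 / (s0 + KMS * (1 + i0 / KMI)),
    refined = function(s0, i0, e0, vmax, KMS, KMI, umax = NA)
      vmax * s0 / (s0 + e0 + KMS * (1 + i0 / (e0 + KMI))),
    partial_refined = function(s0, i0, e0, vmax, KMS, KDI, umax = NA)
      vmax * s0 / (s0 + e0 + KMS * (1 + i0 / (e0 + KDI))),
    partial_cubicroot = function(s0, i0, e0, vmax, KMS, KDI, umax = NA) {
      mu_S <- KMS / s0
      kap_I <- KDI / i0
      eps_I <- e0 / i0
      beta_I <- 1 + eps_I + kap_I
      h <- sqrt((kap_I + mu_S * beta_I)^2 - 4 * eps_I * mu_S^2)
      Y1 <- (kap_I + mu_S * beta_I - h) / (2 * eps_I * mu_S)
      vmax * (1 - Y1) / (1 + mu_S)
    },
    stop("unknown model: ", model, call. = FALSE))
}

.velocity_law_u <- function(model) {
  switch(model,
    sqssa = function(s0, i0, e0, vmax, KMS, KMI, umax)
      umax * i0 / (i0 + KMI * (1 + s0 / KMS)),
    refined = function(s0, i0, e0, vmax, KMS, KMI, umax)
      umax * i0 / (i0 + e0 + KMI * (1 + s0 / (e0 + KMS))),
    NULL)
}

#' Generate a synthetic steady-state velocity dataset
#'
#' Emulates a series of velocity-versus-substrate steady-state experiments
#' at several inhibitor concentrations. For each `(s0, i0)` design point the
#' steady velocities are taken either from a full reference simulation of
#' the dimensional system (reading the prolonged steady-state event, the
#' full-fledged one when a channel is multi-steady) or from a named closed
#' form, then perturbed by multiplicative Gaussian noise on the relative
#' scale (truncated at -90%, since measured velocities scale with signal).
#'
#' @param true_params A [dimensional_params()] object (the ground truth).
#' @param s0,i0 Design axes (crossed into a grid, M).
#' @param noise_sd Relative noise standard deviation (0 for noiseless).
#' @param seed Integer seed; the dataset is deterministic given the seed.
#' @param velocity_source `"simulation"` or `"closed_form"`.
#' @param closed_form Which law to use for `velocity_source =
#'   "closed_form"`: `"refined"`, `"sqssa"` or `"partial_refined"`.
#' @return A tibble `s0, i0, v, u` (u is NA for the partial scheme) with
#'   attributes `true_params`, `noise_sd`, `seed`, `source`. Design points
#'   whose simulation fails are dropped (recorded in attribute
#'   `"dropped"`).
#' @export
generate_velocity_dataset <- function(true_params, s0, i0, noise_sd = 0.05,
                                      seed = 1,
                                      velocity_source = c("simulation",
                                                          "closed_form"),
                                      closed_form = "refined") {
  stopifnot(inherits(true_params, "ciket_dimensional"))
  velocity_source <- match.arg(velocity_source)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  design <- tidyr::expand_grid(s0 = s0, i0 = i0)
  if (!nrow(design)) stop("empty design", call. = FALSE)
  d <- true_params
  vmax <- d$k2 * d$e0
  umax <- d$k3 * d$e0
  KMS <- (d$k2 + d$k_m1) / d$k1
  KMI <- if (d$k3 > 0) (d$k3 + d$k_mi) / d$ki else NA_real_
  KDI <- d$k_mi / d$ki
  dropped <- integer()
  if (velocity_source == "closed_form") {
    law <- .velocity_law(closed_form)
    Ki <- if (closed_form == "partial_refined") KDI else KMI
    v <- law(design$s0, design$i0, d$e0, vmax, KMS, Ki)
    ulaw <- .velocity_law_u(closed_form)
    u <- if (!is.null(ulaw) && d$k3 > 0)
      ulaw(design$s0, design$i0, d$e0, vmax, KMS, KMI, umax)
    else rep(NA_real_, nrow(design))
  } else {
    res <- purrr::map(seq_len(nrow(design)), function(i) {
      di <- d
      di$s0 <- design$s0[i]
      di$i0 <- design$i0[i]
      di <- do.call(dimensional_params, di)
      tryCatch({
        if (d$k3 == 0) {
          pp <- nondimensionalize(di)
          traj <- simulate_partial(pp)
          ev <- detect_steady_states(traj)
          mx <- ev[ev$channel == "substrate" & ev$type == "maximum", ]
          c(v = d$k2 * d$e0 * mx$X[nrow(mx)], u = NA_real_)
        } else {
          p <- nondimensionalize(di)
          traj <- simulate_full(p)
          ev <- detect_steady_states(traj)
          mxS <- ev[ev$channel == "substrate" & ev$type == "maximum", ]
          mxI <- ev[ev$channel == "inhibitor" & ev$type == "maximum", ]
          c(v = d$k2 * d$e0 * mxS$X[nrow(mxS)],
            u = d$k3 * d$e0 * mxI$Y[nrow(mxI)])
        }
      }, error = function(e) c(v = NA_real_, u = NA_real_))
    })
    v <- purrr::map_dbl(res, "v")
    u <- purrr::map_dbl(res, "u")
    dropped <- which(is.na(v))
  }
  out <- tibble::tibble(s0 = design$s0, i0 = design$i0, v = v, u = u)
  if (length(dropped)) out <- out[-dropped, ]
  if (noise_sd > 0) {
    out <- withr::with_seed(seed, {
      f_v <- pmax(1 + stats::rnorm(nrow(out), 0, noise_sd), 0.1)
      f_u <- pmax(1 + stats::rnorm(nrow(out), 0, noise_sd), 0.1)
      dplyr::mutate(out, v = .data$v * f_v, u = .data$u * f_u)
    })
  }
  attr(out, "true_params") <- true_params
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  attr(out, "source") <- velocity_source
  attr(out, "dropped") <- dropped
  out
}

#' Fit a steady-state velocity law to a dataset
#'
#' Trust-region nonlinear least squares ([minpack.lm::nls.lm()]) on
#' log-parameters (positivity by construction) with seeded multi-start
#' against local minima. Models: classical sQSSA (`v_max, K_MS, K_MI`),
#' refined sQSSA with the `e0` corrections, and the partial-scheme refined
#' and quadratic-root laws (`v_max, K_MS, K_DI`). When the dataset carries
#' inhibitor-product velocities `u` and the model family supports them, v
#' and u are fitted jointly (adding `u_max`). Standard errors come from a
#' case-resampling bootstrap.
#'
#' @param data A tibble with columns `s0, i0, v` (optionally `u`).
#' @param model `"sqssa"`, `"refined"`, `"partial_refined"` or
#'   `"partial_cubicroot"`.
#' @param e0 Known total enzyme concentration (M), as in experiments.
#' @param n_boot Bootstrap replicates for standard errors (0 to skip).
#' @param n_starts Multi-start count.
#' @param seed Seed for starts and bootstrap.
#' @return A `ciket_fit` object; see [tidy.ciket_fit()] and
#'   [glance.ciket_fit()].
#' @export
fit_velocity_model <- function(data, model = c("refined", "sqssa",
                                               "partial_refined",
                                               "partial_cubicroot"),
                               e0, n_boot = 200, n_starts = 5, seed = 1) {
  model <- match.arg(model)
  stopifnot(all(c("s0", "i0", "v") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("s0", "i0", "v")]), ]
  law_v <- .velocity_law(model)
  law_u <- .velocity_law_u(model)
  use_u <- !is.null(law_u) && "u" %in% names(data) && !anyNA(data$u)
  pnames <- c("vmax", "KMS", if (startsWith(model, "partial")) "KDI"
              else "KMI", if (use_u) "umax")
  if (nrow(data) < length(pnames)) {
    stop("need at least as many records as free parameters", call. = FALSE)
  }
  resid_fn <- function(logpar, dat) {
    th <- exp(logpar)
    r <- dat$v - law_v(dat$s0, dat$i0, e0, th[1], th[2], th[3])
    if (use_u) {
      r <- c(r, dat$u - law_u(dat$s0, dat$i0, e0, th[1], th[2], th[3],
                              th[4]))
    }
    r
  }
  base_start <- log(c(vmax = max(data$v) * 2, KMS = stats::median(data$s0),
                      K_i = stats::median(data$i0),
                      if (use_u) c(umax = max(data$u) * 2)))
  one_fit <- function(dat, starts) {
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        minpack.lm::nls.lm(st, fn = resid_fn, dat = dat,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    best
  }
  starts <- withr::with_seed(seed, c(
    list(base_start),
    purrr::map(seq_len(max(0, n_starts - 1)), function(i)
      base_start + stats::rnorm(length(base_start), 0, 1))))
  fit <- one_fit(data, starts)
  if (is.null(fit)) stop("optimizer failed from every start", call. = FALSE)
  est <- exp(fit$par)
  names(est) <- pnames
  boot <- NULL
  if (n_boot > 0) {
    boot <- withr::with_seed(seed + 1, {
      reps <- purrr::map(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(data), replace = TRUE)
        bf <- one_fit(data[idx, ], list(fit$par))
        if (is.null(bf)) rep(NA_real_, length(est)) else exp(bf$par)
      })
      do.call(rbind, reps)
    })
  }
  se <- if (!is.null(boot)) apply(boot, 2, stats::sd, na.rm = TRUE)
  else rep(NA_real_, length(est))
  structure(list(
    estimates = tibble::tibble(term = pnames, estimate = unname(est),
                               std.error = unname(se)),
    model = model, e0 = e0, data = data, use_u = use_u,
    deviance = fit$deviance, niter = fit$niter,
    converged = fit$info %in% 1:4, info = fit$info,
    message = fit$message, n_boot = n_boot,
    boot = boot), class = "ciket_fit")
}

#' @export
print.ciket_fit <- function(x, ...) {
  cat(sprintf("<ciket velocity fit: model %s, n = %d%s>\n", x$model,
              nrow(x$data), if (x$use_u) ", joint (v, u)" else ""))
  print(x$estimates)
  cat(sprintf("deviance %.4g, %s (%d iterations)\n", x$deviance,
              if (x$converged) "converged" else
                paste0("NOT converged: ", x$message), x$niter))
  invisible(x)
}

#' Tidy a velocity fit
#'
#' @param x A `ciket_fit`.
#' @param ... Unused.
#' @return A tibble with `term, estimate, std.error`.
#' @exportS3Method generics::tidy
tidy.ciket_fit <- function(x, ...) x$estimates

#' One-row fit summary
#'
#' @param x A `ciket_fit`.
#' @param ... Unused.
#' @return A tibble with model id, number of records, residual deviance,
#'   convergence flag and bootstrap size.
#' @export
glance.ciket_fit <- function(x, ...) {
  tibble::tibble(model = x$model, nobs = nrow(x$data),
                 deviance = x$deviance, converged = x$converged,
                 n_boot = x$n_boot)
}

#' Fitted velocities of a velocity fit
#'
#' @param object A `ciket_fit`.
#' @param ... Unused.
#' @return Numeric vector of fitted v values (the v-channel only).
#' @export
fitted.ciket_fit <- function(object, ...) {
  th <- object$estimates$estimate
  .velocity_law(object$model)(object$data$s0, object$data$i0, object$e0,
                              th[1], th[2], th[3])
}
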