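# Config parsing and trajectory serialization shared by the CLI wrapper.

.config_keys <- list(
  top = c("scheme", "dimensional", "dimensionless", "integrator", "output",
          "seed", "verbose"),
  dimensional = c("k1", "k_m1", "k2", "ki", "k_mi", "k3", "e0", "s0", "i0"),
  dimless_full = c("eta_S", "eps_S", "kappa_S", "eta_I", "eps_I", "kappa_I",
                   "rho", "sigma"),
  dimless_partial = c("eta_S", "eps_S", "kappa_S", "chi_I", "eps_I",
                      "kappa_I"),
  integrator = c("method", "dtau", "tau_end", "n_out"))

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration with either a `dimensional:` block
#' (rate constants and concentrations) or a `dimensionless:` block, plus
#' optional `integrator:` settings, `seed` and `scheme`. Unknown keys are
#' rejected with named diagnostics; exactly one parameter block must be
#' present. A dimensionless block containing `sigma` but no `rho` is closed
#' via [close_parameters()].
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list of class `ciket_config` with elements `params` (a
#'   parameter object), `scheme`, `integrator`, `seed`, `verbose`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop(sprintf("unknown %s key(s): %s", where,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_keys(cfg, .config_keys$top, "top-level")
  has_dim <- !is.null(cfg$dimensional)
  has_dml <- !is.null(cfg$dimensionless)
  if (has_dim == has_dml) {
    stop("exactly one of 'dimensional:' or 'dimensionless:' must be given",
         call. = FALSE)
  }
  if (has_dim) {
    check_keys(cfg$dimensional, .config_keys$dimensional, "dimensional")
    d <- do.call(dimensional_params, cfg$dimensional)
    params <- nondimensionalize(d)
  } else {
    b <- cfg$dimensionless
    if (!is.null(b$chi_I)) {
      check_keys(b, .config_keys$dimless_partial, "dimensionless (partial)")
      params <- do.call(partial_dimless, b)
    } else {
      check_keys(b, .config_keys$dimless_full, "dimensionless")
      sigma <- b$sigma
      b$sigma <- NULL
      params <- do.call(full_dimless, b)
      if (is.na(params$rho)) {
        params <- close_parameters(params, sigma = sigma %||% 1)
      }
    }
  }
  integ <- cfg$integrator %||% list()
  check_keys(integ, .config_keys$integrator, "integrator")
  integ <- utils::modifyList(
    list(method = "reference", dtau = 1e-5, tau_end = NULL, n_out = 4000),
    integ)
  scheme <- cfg$scheme %||%
    if (inherits(params, "ciket_partial_dimless")) "partial" else "full"
  structure(list(params = params, scheme = scheme, integrator = integ,
                 seed = cfg$seed %||% 1L, verbose = isTRUE(cfg$verbose)),
            class = "ciket_config")
}

#' Write a trajectory to CSV or JSON
#'
#' Output is bit-stable for fixed inputs: columns in canonical order,
#' floats at 10 significant digits, JSON keys sorted by construction. The
#' JSON format carries the scheme tag and the parameter snapshot; CSV
#' stores the table only.
#'
#' @param traj A `ciket_trajectory`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, TRUE)
  if (format == "csv") {
    fmt <- df
    fmt[num] <- lapply(fmt[num], function(x) sprintf("%.10g", x))
    utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(
      scheme = attr(traj, "scheme"),
      method = attr(traj, "method"),
      params = unclass(attr(traj, "params")),
      trajectory = lapply(df[num], function(x)
        as.numeric(sprintf("%.10g", x))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path Path to a CSV or JSON trajectory file.
#' @return A `ciket_trajectory` (JSON restores scheme and parameters; CSV
#'   restores the table only).
#' @export
read_trajectory <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- tibble::as_tibble(payload$trajectory)
    params <- payload$params
    class(params) <- if (identical(payload$scheme, "partial"))
      "ciket_partial_dimless" else "ciket_full_dimless"
    .new_trajectory(df, payload$scheme, params, payload$method)
  } else {
    df <- tibble::as_tibble(utils::read.csv(path))
    .new_trajectory(df, NA_character_, NULL, NA_character_)
  }
}
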