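#' Assemble a simulation configuration
#'
#' Bundles everything one run needs: colony size and duration, the caste
#' regime with its trait distributions, the nest-leaving distribution and
#' the global rates. Defaults follow the reference study conditions: a
#' 53-worker colony observed for 3600 one-second timesteps, Hill
#' parameters `n = 2` and `k = 120` food units (the half-saturation crop
#' load, matching the mean quantity of food exchanged per trophallactic
#' event), and rate parameters calibrated so that the two-emergent-caste
#' exponential regime reproduces the reference foraging statistics (about
#' 99 events and 12.5 foragers per hour; see the package vignette).
#'
#' @param n_ants Colony size (default 53 workers).
#' @param n_steps Number of one-second timesteps (default 3600, one hour).
#' @param regime A [caste_regime()]; default the two-emergent-caste
#'   exponential regime with reference giving/receiving means.
#' @param alpha An [alpha_spec()] for the nest-leaving maxima; default a
#'   bounded power law calibrated to the reference forager count.
#' @param beta Per-second probability of leaving the food source (inverse
#'   of the mean feeding-bout duration).
#' @param phi Per-second probability that an ongoing trophallactic pair
#'   separates (inverse of the mean event duration).
#' @param intake_rate Food units ingested per second at the source.
#' @param transfer_rate Food units transferred donor to receiver per
#'   second of trophallaxis. Together with `phi` this sets the mean
#'   amount exchanged per event (`transfer_rate / phi` when the donor
#'   does not empty); the default is calibrated jointly with the other
#'   rates (see the vignette).
#' @param k Half-saturation crop load, food units.
#' @param n Hill steepness.
#' @param return_delay Timesteps spent in transit between source and nest
#'   (0 = instantaneous return).
#' @param traj_every Record each ant's crop load every `traj_every` steps
#'   (0 disables the trajectory).
#' @param pairing_before_departures Swap the within-step order of the
#'   pairing and departure phases (sensitivity flag; default `FALSE`).
#' @param dual_initiation Encounter model: each unpaired nest ant
#'   initiates one encounter per second as a potential donor and, if that
#'   fails, one as a potential receiver (`TRUE`, default, matching the
#'   description of individuals engaging in exchanges in either role);
#'   `FALSE` restricts each ant to the donor-side attempt only.
#' @return A `sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(n_ants = 20, n_steps = 600)
#' res <- run_simulation(cfg, seed = 1)
#' @export
sim_config <- function(n_ants = 53, n_steps = 3600,
                       regime = NULL, alpha = NULL,
                       beta = 1 / 15, phi = 0.06,
                       intake_rate = 25, transfer_rate = 27,
                       k = 120, n = 2,
                       return_delay = 0, traj_every = 0,
                       pairing_before_departures = FALSE,
                       dual_initiation = TRUE) {
  if (is.null(regime)) regime <- preset_regime("TEC", "exponential")
  if (is.null(alpha)) alpha <- default_alpha_spec()
  stopifnot(inherits(regime, "caste_regime"), inherits(alpha, "alpha_spec"))
  if (!(n_ants > 1)) stop("n_ants must be > 1", call. = FALSE)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  for (p in c(beta = beta, phi = phi)) {
    if (!is.finite(p) || p <= 0 || p > 1) {
      stop("beta and phi must be probabilities in (0, 1]", call. = FALSE)
    }
  }
  if (intake_rate <= 0 || transfer_rate <= 0) {
    stop("intake_rate and transfer_rate must be > 0", call. = FALSE)
  }
  if (k <= 0 || n <= 0) stop("k and n must be > 0", call. = FALSE)
  structure(list(
    n_ants = as.integer(n_ants), n_steps = as.integer(n_steps),
    regime = regime, alpha = alpha,
    beta = beta, phi = phi,
    intake_rate = intake_rate, transfer_rate = transfer_rate,
    k = k, n = n,
    return_delay = as.integer(return_delay),
    traj_every = as.integer(traj_every),
    pairing_before_departures = isTRUE(pairing_before_departures),
    dual_initiation = isTRUE(dual_initiation)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_ants, " ants, ", x$n_steps, " timesteps\n", sep = "")
  cat("  regime: ", x$regime$kind,
      " (theta_F ", format(x$regime$theta_f$mean, digits = 3),
      ", theta_NF ", format(x$regime$theta_nf$mean, digits = 3),
      ", gamma_F ", format(x$regime$gamma_f$mean, digits = 3),
      ", gamma_NF ", format(x$regime$gamma_nf$mean, digits = 3), ")\n", sep = "")
  cat("  beta ", format(x$beta, digits = 3), ", phi ", format(x$phi, digits = 3),
      ", intake ", format(x$intake_rate), ", transfer ", format(x$transfer_rate),
      ", k ", format(x$k), ", n ", format(x$n), "\n", sep = "")
  invisible(x)
}

# Reference giving/receiving population means (probability per
# second) for each model version x trait distribution. In the one-caste
# version foragers and non-foragers share one pair of means.
reference_means <- function(model, distribution) {
  key <- paste(model, distribution, sep = ".")
  switch(key,
    OC.delta       = list(theta_f = 1/11, gamma_f = 1/60),
    OC.uniform     = list(theta_f = 1/10, gamma_f = 1/50),
    OC.exponential = list(theta_f = 1/6,  gamma_f = 1/56),
    TEC.delta       = list(theta_f = 1/10, theta_nf = 1/33,
                           gamma_f = 1/11, gamma_nf = 1/38),
    TEC.uniform     = list(theta_f = 1/11, theta_nf = 1/32,
                           gamma_f = 1/9,  gamma_nf = 1/28),
    TEC.exponential = list(theta_f = 1/9,  theta_nf = 1/23,
                           gamma_f = 1/9,  gamma_nf = 1/27),
    stop("unknown model/distribution combination", call. = FALSE)
  )
}

#' Reference caste regimes
#'
#' Builds the [caste_regime()] for one of the six studied model variants:
#' one-caste (`"OC"`) or two-emergent-caste (`"TEC"`), each with
#' `"delta"`, `"uniform"` or `"exponential"` trait heterogeneity, using
#' the reference giving/receiving population means for that variant.
#'
#' @param model `"TEC"` or `"OC"`.
#' @param distribution `"delta"`, `"uniform"` or `"exponential"`.
#' @return A `caste_regime`.
#' @examples
#' preset_regime("OC", "delta")
#' @export
preset_regime <- function(model = c("TEC", "OC"),
                          distribution = c("exponential", "delta", "uniform")) {
  model <- match.arg(model)
  distribution <- match.arg(distribution)
  m <- reference_means(model, distribution)
  if (model == "OC") {
    caste_regime("OC",
                 theta_nf = trait_spec(distribution, m$theta_f),
                 gamma_nf = trait_spec(distribution, m$gamma_f))
  } else {
    caste_regime("TEC",
                 theta_nf = trait_spec(distribution, m$theta_nf),
                 gamma_nf = trait_spec(distribution, m$gamma_nf),
                 theta_f  = trait_spec(distribution, m$theta_f),
                 gamma_f  = trait_spec(distribution, m$gamma_f))
  }
}

#' Default nest-leaving distribution
#'
#' Bounded power law for the first-departure maxima, calibrated (jointly
#' with the rate defaults of [sim_config()]) so that about 12 of 53
#' workers visit the source at least once within an hour; see the
#' vignette for the calibration procedure.
#'
#' @return An [alpha_spec()].
#' @export
default_alpha_spec <- function() {
  alpha_spec("power_law", exponent = 1.8,
             min_value = 2e-5, max_value = 0.3,
             forager_multiplier = 1.5)
}

#' Convenience constructor for the six studied model variants
#'
#' @param model,distribution Passed to [preset_regime()].
#' @param ... Further arguments to [sim_config()].
#' @return A `sim_config`.
#' @examples
#' preset_config("OC", "delta", n_steps = 600)
#' @export
preset_config <- function(model = c("TEC", "OC"),
                          distribution = c("exponential", "delta", "uniform"),
                          ...) {
  sim_config(regime = preset_regime(model, distribution), ...)
}

#' Serialize / restore a configuration
#'
#' Round-trips a [sim_config()] through a plain named list (YAML/JSON
#' friendly), as written into run provenance headers.
#'
#' @param config A `sim_config`.
#' @return `config_to_list()`: a named list of plain values;
#'   `config_from_list()`: a `sim_config`.
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec_list <- function(s) list(kind = s$kind, mean = s$mean)
  list(
    n_ants = config$n_ants, n_steps = config$n_steps,
    model = config$regime$kind,
    theta_nf = spec_list(config$regime$theta_nf),
    gamma_nf = spec_list(config$regime$gamma_nf),
    theta_f = spec_list(config$regime$theta_f),
    gamma_f = spec_list(config$regime$gamma_f),
    alpha = list(kind = config$alpha$kind, exponent = config$alpha$exponent,
                 min_value = config$alpha$min_value,
                 max_value = config$alpha$max_value,
                 forager_multiplier = config$alpha$forager_multiplier),
    beta = config$beta, phi = config$phi,
    intake_rate = config$intake_rate, transfer_rate = config$transfer_rate,
    k = config$k, n = config$n,
    return_delay = config$return_delay, traj_every = config$traj_every,
    pairing_before_departures = config$pairing_before_departures,
    dual_initiation = config$dual_initiation
  )
}

#' @rdname config_to_list
#' @param x A named list as produced by `config_to_list()` (or read from
#'   a YAML/JSON run config).
#' @export
config_from_list <- function(x) {
  spec_of <- function(s) trait_spec(s$kind, s$mean)
  regime <- if (identical(x$model, "OC")) {
    caste_regime("OC", theta_nf = spec_of(x$theta_nf), gamma_nf = spec_of(x$gamma_nf))
  } else {
    caste_regime("TEC", theta_nf = spec_of(x$theta_nf), gamma_nf = spec_of(x$gamma_nf),
                 theta_f = spec_of(x$theta_f), gamma_f = spec_of(x$gamma_f))
  }
  alpha <- alpha_spec(x$alpha$kind, exponent = x$alpha$exponent,
                      min_value = x$alpha$min_value, max_value = x$alpha$max_value,
                      forager_multiplier = x$alpha$forager_multiplier)
  sim_config(n_ants = x$n_ants, n_steps = x$n_steps, regime = regime,
             alpha = alpha, beta = x$beta, phi = x$phi,
             intake_rate = x$intake_rate, transfer_rate = x$transfer_rate,
             k = x$k, n = x$n, return_delay = x$return_delay,
             traj_every = x$traj_every,
             pairing_before_departures = isTRUE(x$pairing_before_departures),
             dual_initiation = isTRUE(x$dual_initiation))
}

#' Read / write a run configuration file
#'
#' YAML by default; files ending in `.json` are read and written as JSON.
#'
#' @param path File path.
#' @return `read_run_config()` returns a `sim_config`.
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(x)
}

#' @rdname read_run_config
#' @param config A `sim_config` to write.
#' @export
write_run_config <- function(config, path) {
  x <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}
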