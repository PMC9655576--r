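#' Run one colony simulation
#'
#' Draws the colony's trait table, then advances the colony state
#' timestep by timestep: ongoing trophallactic pairs transfer food and
#' may separate; unpaired ants in the nest may leave for the source
#' (first departures promote to forager); ants at the source ingest food
#' and may return; unpaired nest ants may form new donor-receiver pairs
#' with probability `theta_i(Q_i) * gamma_j(Q_j)`. All ants start in the
#' nest as non-foragers with empty crops; the food source is unlimited.
#'
#' Runs are fully reproducible: the same `(config, seed)` yields a
#' bit-identical event log.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for all randomness in the run.
#' @return A `troph_sim` object with components
#'   * `events`: tibble of trophallactic events (`donor`, `receiver`,
#'     `t_start`, `t_end`, `amount`, `donor_caste`, `receiver_caste`,
#'     castes as of the event start);
#'   * `ants`: per-ant tibble (`id`, `caste` at the end of the run,
#'     `first_visit` timestep or `NA`, final `crop`, `max_stay` = longest
#'     uninterrupted feeding bout at the source, plus the drawn traits);
#'   * `forager_ids`: ids of ants that visited the source at least once;
#'   * `withdrawn`: total food taken from the source;
#'   * `crop_trajectory`: matrix of crop loads (ants x snapshots) when
#'     `traj_every > 0`;
#'   * `config`, `seed`.
#' @examples
#' res <- run_simulation(sim_config(n_ants = 20, n_steps = 600), seed = 1)
#' nrow(res$events)
#' @export
run_simulation <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  traits <- draw_colony_traits(config$n_ants, config$regime, config$alpha)
  raw <- simulate_colony_cpp(
    config$n_steps,
    traits$theta0_nf, traits$gamma0_nf, traits$theta0_f, traits$gamma0_f,
    traits$alpha0, traits$alpha0_forager,
    config$k, config$n, config$beta, config$phi,
    config$intake_rate, config$transfer_rate, config$return_delay,
    config$traj_every, TRUE, config$pairing_before_departures,
    config$dual_initiation
  )
  caste_lab <- function(x) c("NF", "F")[x + 1L]
  events <- tibble::tibble(
    donor = raw$donor, receiver = raw$receiver,
    t_start = raw$t_start, t_end = raw$t_end, amount = raw$amount,
    donor_caste = caste_lab(raw$donor_caste),
    receiver_caste = caste_lab(raw$receiver_caste)
  )
  ants <- dplyr::mutate(traits,
    caste = caste_lab(raw$caste),
    first_visit = raw$first_visit,
    crop = raw$crop,
    max_stay = raw$max_stay
  )
  structure(list(
    events = events,
    ants = ants,
    forager_ids = ants$id[!is.na(ants$first_visit)],
    withdrawn = raw$withdrawn,
    max_conservation_dev = raw$max_conservation_dev,
    crop_trajectory = if (config$traj_every > 0) raw$traj else NULL,
    config = config, seed = as.integer(seed)
  ), class = "troph_sim")
}

#' @export
print.troph_sim <- function(x, ...) {
  cat("<troph_sim> ", x$config$regime$kind, " colony of ", x$config$n_ants,
      " ants, ", x$config$n_steps, " timesteps (seed ", x$seed, ")\n", sep = "")
  cat("  ", nrow(x$events), " trophallactic events, ",
      length(x$forager_ids), " foragers, ",
      format(x$withdrawn), " food units withdrawn\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn run_simulation `tidy()` returns the event log as a tibble.
#' @param x A `troph_sim`.
#' @param ... Unused.
#' @export
tidy.troph_sim <- function(x, ...) x$events

#' @describeIn run_simulation `glance()` returns a one-row tibble of
#'   summary statistics (see [summarize_simulation()]).
#' @export
glance.troph_sim <- function(x, ...) summarize_simulation(x)

#' Run an ensemble of replicate simulations
#'
#' Repeats [run_simulation()] `n_reps` times with per-replicate seeds
#' `base_seed + 1, ..., base_seed + n_reps`, and summarises each
#' replicate.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates (the reference protocol used 1000;
#'   200 give a standard error of about 1 event on the mean count).
#' @param base_seed Integer; replicate `i` uses seed `base_seed + i`.
#' @param keep_results Keep the individual `troph_sim` objects (`TRUE`) or
#'   only the per-replicate summary rows (`FALSE`, lighter).
#' @return A `troph_ensemble` with `summaries` (tibble, one row per
#'   replicate, see [summarize_simulation()]), optionally `results`, plus
#'   `config` and `base_seed`.
#' @examples
#' ens <- run_ensemble(sim_config(n_ants = 20, n_steps = 600), n_reps = 4,
#'                     base_seed = 0)
#' glance(ens)
#' @export
run_ensemble <- function(config, n_reps, base_seed = 0, keep_results = FALSE) {
  stopifnot(n_reps >= 1)
  results <- vector("list", n_reps)
  summaries <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    res <- run_simulation(config, seed = base_seed + i)
    summaries[[i]] <- dplyr::mutate(summarize_simulation(res),
                                    rep = i, seed = res$seed, .before = 1)
    if (keep_results) results[[i]] <- res
  }
  structure(list(
    summaries = dplyr::bind_rows(summaries),
    results = if (keep_results) results else NULL,
    config = config, base_seed = base_seed, n_reps = n_reps
  ), class = "troph_ensemble")
}

#' @export
print.troph_ensemble <- function(x, ...) {
  cat("<troph_ensemble> ", x$n_reps, " replicates of a ",
      x$config$regime$kind, " colony (", x$config$n_ants, " ants, ",
      x$config$n_steps, " timesteps)\n", sep = "")
  cat("  mean events ", format(mean(x$summaries$n_events), digits = 4),
      ", mean foragers ", format(mean(x$summaries$n_foragers), digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn run_ensemble `tidy()` returns the per-replicate summary
#'   table.
#' @param x A `troph_ensemble`.
#' @param ... Unused.
#' @export
tidy.troph_ensemble <- function(x, ...) x$summaries

#' @describeIn run_ensemble `glance()` returns one row of ensemble means
#'   and standard deviations of the main statistics.
#' @export
glance.troph_ensemble <- function(x, ...) {
  s <- x$summaries
  tibble::tibble(
    n_reps = nrow(s),
    mean_events = mean(s$n_events), sd_events = stats::sd(s$n_events),
    mean_foragers = mean(s$n_foragers), sd_foragers = stats::sd(s$n_foragers),
    mean_nf_donation_share = mean(s$nf_donation_share, na.rm = TRUE),
    mean_gini = mean(s$gini, na.rm = TRUE),
    mean_t50 = mean(s$t50, na.rm = TRUE),
    mean_efficiency = mean(s$efficiency, na.rm = TRUE)
  )
}

#' Event log of a simulation written to / read from CSV
#'
#' @param sim A `troph_sim` (or a tibble of events with a `rep` column).
#' @param path Output CSV path.
#' @export
write_event_log <- function(sim, path) {
  events <- if (inherits(sim, "troph_sim")) sim$events else sim
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
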