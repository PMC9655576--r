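#' Scan-sample a raw event log
#'
#' Applies the behavioural-observation protocol to a continuous
#' (per-second) event log: the observer scans the colony once per minute
#' (at timesteps `scan_interval, 2 * scan_interval, ...`) and notes every
#' ongoing trophallactic contact, ignoring events whose total duration is
#' not longer than `min_duration` seconds. Observations of the same
#' ordered (donor, receiver) pair on consecutive scans are merged into a
#' single observed event whose duration is the number of scans. The same
#' two ants with reversed roles count as a different pair, since food
#' flow cannot reverse within an event.
#'
#' @param events Raw event tibble (`donor`, `receiver`, `t_start`,
#'   `t_end`; durations in timesteps are `t_end - t_start + 1`).
#' @param scan_interval Seconds between scans (default 60).
#' @param min_duration Events lasting `<= min_duration` seconds are never
#'   recorded (default 5; the threshold is strict).
#' @return A tibble of observed events: `donor`, `receiver`,
#'   `first_scan_minute` (index of the first scan seeing the pair),
#'   `duration_minutes` (number of consecutive scans).
#' @examples
#' ev <- tibble::tibble(donor = 1, receiver = 2, t_start = 115, t_end = 185)
#' scan_sample(ev)  # one event of 2 minutes
#' @export
scan_sample <- function(events, scan_interval = 60, min_duration = 5) {
  empty <- tibble::tibble(donor = integer(), receiver = integer(),
                          first_scan_minute = integer(),
                          duration_minutes = integer())
  if (nrow(events) == 0) return(empty)
  ev <- events |>
    dplyr::mutate(duration = .data$t_end - .data$t_start + 1) |>
    dplyr::filter(.data$duration > min_duration) |>
    dplyr::mutate(
      first_scan = ceiling(.data$t_start / scan_interval),
      last_scan = floor(.data$t_end / scan_interval)
    ) |>
    dplyr::filter(.data$last_scan >= .data$first_scan, .data$first_scan >= 1)
  if (nrow(ev) == 0) return(empty)
  # one row per (pair, scan), deduplicated, then runs of consecutive
  # scans of the same ordered pair collapse into one observed event
  ev |>
    dplyr::mutate(scan = purrr::map2(.data$first_scan, .data$last_scan, seq)) |>
    tidyr::unnest("scan") |>
    dplyr::distinct(.data$donor, .data$receiver, .data$scan) |>
    dplyr::arrange(.data$donor, .data$receiver, .data$scan) |>
    dplyr::group_by(.data$donor, .data$receiver) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$scan) != 1L))) |>
    dplyr::group_by(.data$donor, .data$receiver, .data$run) |>
    dplyr::summarise(first_scan_minute = min(.data$scan),
                     duration_minutes = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$first_scan_minute, .data$donor, .data$receiver)
}

#' Classify events by the castes of their participants
#'
#' Partitions an event log into the four pair types F->F, F->NF, NF->F
#' and NF->NF, using each participant's caste at the moment the event
#' started. If the log carries `donor_caste` / `receiver_caste` columns
#' these are used directly; otherwise castes are resolved from the ants'
#' first source-visit times (`F` iff `first_visit <= t_start`).
#'
#' @param events Event tibble.
#' @param first_visit_times Optional named vector (names = ant ids) of
#'   first-visit timesteps, `NA` for ants that never visited; required
#'   when the log has no caste columns.
#' @return A tibble with columns `pair_type` (`"F_F"`, `"F_NF"`,
#'   `"NF_F"`, `"NF_NF"`), `count` and `proportion`; counts sum to the
#'   number of events.
#' @export
classify_pair_types <- function(events, first_visit_times = NULL) {
  lv <- c("F_F", "F_NF", "NF_F", "NF_NF")
  if (nrow(events) == 0) {
    return(tibble::tibble(pair_type = lv, count = 0L, proportion = NA_real_))
  }
  if (!all(c("donor_caste", "receiver_caste") %in% names(events))) {
    if (is.null(first_visit_times)) {
      stop("need caste columns or first_visit_times", call. = FALSE)
    }
    ids <- names(first_visit_times)
    if (!all(as.character(c(events$donor, events$receiver)) %in% ids)) {
      stop("event participants missing from first_visit_times", call. = FALSE)
    }
    caste_at <- function(id, t) {
      fv <- first_visit_times[as.character(id)]
      ifelse(!is.na(fv) & fv <= t, "F", "NF")
    }
    events$donor_caste <- caste_at(events$donor, events$t_start)
    events$receiver_caste <- caste_at(events$receiver, events$t_start)
  }
  type <- factor(paste(events$donor_caste, events$receiver_caste, sep = "_"),
                 levels = lv)
  if (anyNA(type)) stop("unknown caste labels in event log", call. = FALSE)
  counts <- as.integer(table(type))
  tibble::tibble(pair_type = lv, count = counts,
                 proportion = counts / sum(counts))
}

#' Generate a synthetic experiment in the field-observation format
#'
#' Stands in for real scan-sampled colony recordings: simulates
#' `n_colonies` independent colonies (by default under the
#' two-emergent-caste exponential regime), pushes each raw event log
#' through [scan_sample()], and returns (optionally writes) the two
#' tables an observational study would produce — a per-minute event
#' table and a worker metadata table. A worker is flagged as a forager if
#' it spent at least `forager_feed_threshold` consecutive seconds feeding
#' at the source. All outputs are synthetic; they emulate the format of
#' real recordings, not any particular dataset.
#'
#' @param n_colonies Number of colonies (default 5).
#' @param config A [sim_config()] describing each colony (default: the
#'   two-emergent-caste exponential preset, 50 workers as in typical
#'   observation sub-colonies).
#' @param seed Integer; colony `i` is simulated with seed `seed + i`.
#' @param dir Optional directory: writes `events.csv` (columns `colony`,
#'   `minute`, `donor`, `receiver`, one row per observed minute) and
#'   `workers.csv` (`colony`, `ant_id`, `is_forager`).
#' @param scan_interval,min_duration Passed to [scan_sample()].
#' @param forager_feed_threshold Consecutive feeding seconds required for
#'   the forager flag (default 5).
#' @return List of tibbles `events` (colony, minute, donor, receiver),
#'   `observed` (merged observed events with durations), `workers`, and
#'   `raw` (the per-colony raw event counts).
#' @export
generate_synthetic_experiment <- function(n_colonies = 5, config = NULL,
                                          seed = 1, dir = NULL,
                                          scan_interval = 60, min_duration = 5,
                                          forager_feed_threshold = 5) {
  stopifnot(n_colonies >= 1)
  if (is.null(config)) config <- preset_config("TEC", "exponential", n_ants = 50)
  per_colony <- purrr::map(seq_len(n_colonies), function(i) {
    sim <- run_simulation(config, seed = seed + i)
    obs <- scan_sample(sim$events, scan_interval, min_duration)
    scans <- if (nrow(obs) > 0) {
      obs |>
        dplyr::mutate(minute = purrr::map2(
          .data$first_scan_minute,
          .data$first_scan_minute + .data$duration_minutes - 1L, seq)) |>
        tidyr::unnest("minute") |>
        dplyr::transmute(colony = i, minute = as.integer(.data$minute),
                         donor = .data$donor, receiver = .data$receiver)
    } else {
      tibble::tibble(colony = integer(), minute = integer(),
                     donor = integer(), receiver = integer())
    }
    workers <- tibble::tibble(
      colony = i, ant_id = sim$ants$id,
      is_forager = sim$ants$max_stay >= forager_feed_threshold
    )
    list(scans = scans,
         observed = dplyr::mutate(obs, colony = i, .before = 1),
         workers = workers,
         raw = tibble::tibble(colony = i, n_raw_events = nrow(sim$events)))
  })
  out <- list(
    events = purrr::list_rbind(purrr::map(per_colony, "scans")),
    observed = purrr::list_rbind(purrr::map(per_colony, "observed")),
    workers = purrr::list_rbind(purrr::map(per_colony, "workers")),
    raw = purrr::list_rbind(purrr::map(per_colony, "raw"))
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(out$events, file.path(dir, "events.csv"))
    readr::write_csv(out$workers, file.path(dir, "workers.csv"))
  }
  out
}

#' Read an experimental-format event table
#'
#' Accepts the per-minute scan format (`colony`, `minute`, `donor`,
#' `receiver`; extra columns such as spatial positions are ignored) and
#' merges consecutive-minute records of the same ordered pair into
#' observed events, per colony.
#'
#' @param path CSV path.
#' @return A tibble `colony`, `donor`, `receiver`, `first_scan_minute`,
#'   `duration_minutes`.
#' @export
read_experiment_events <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("colony", "minute", "donor", "receiver")
  if (!all(need %in% names(raw))) {
    stop("experimental event table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  raw |>
    dplyr::distinct(.data$colony, .data$minute, .data$donor, .data$receiver) |>
    dplyr::arrange(.data$colony, .data$donor, .data$receiver, .data$minute) |>
    dplyr::group_by(.data$colony, .data$donor, .data$receiver) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$minute) != 1L))) |>
    dplyr::group_by(.data$colony, .data$donor, .data$receiver, .data$run) |>
    dplyr::summarise(first_scan_minute = min(.data$minute),
                     duration_minutes = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"run")
}
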