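#' Summary statistics of one simulation
#'
#' The statistics used for calibration and for model-experiment
#' comparison: the number of trophallactic events and of foragers, the
#' four pair-type counts and proportions, the share of the donated food
#' volume given by non-foragers, the Gini coefficient of per-ant activity,
#' the time to half the events (T50) and the global network efficiency.
#'
#' @param sim A `troph_sim` from [run_simulation()].
#' @return A one-row tibble with columns `n_events`, `n_foragers`,
#'   `n_F_F`, `n_F_NF`, `n_NF_F`, `n_NF_NF`, `p_F_F`, `p_F_NF`, `p_NF_F`,
#'   `p_NF_NF`, `nf_donation_share`, `gini`, `t50`, `efficiency`.
#'   Quantities undefined on an empty event log are `NA`.
#' @export
summarize_simulation <- function(sim) {
  stopifnot(inherits(sim, "troph_sim"))
  events <- sim$events
  pt <- classify_pair_types(events)
  counts <- stats::setNames(pt$count, paste0("n_", pt$pair_type))
  props <- stats::setNames(pt$proportion, paste0("p_", pt$pair_type))
  roster <- sim$ants[, c("id", "caste")]
  has_events <- nrow(events) > 0
  total_amount <- sum(events$amount)
  nf_share <- if (has_events && total_amount > 0) {
    sum(events$amount[events$donor_caste == "NF"]) / total_amount
  } else NA_real_
  gini <- if (has_events) {
    lorenz_gini(activity_profile(events, roster)$total)$gini
  } else NA_real_
  tibble::tibble(
    n_events = nrow(events),
    n_foragers = length(sim$forager_ids),
    !!!counts, !!!props,
    nf_donation_share = nf_share,
    gini = gini,
    t50 = if (has_events) t50(events) else NA_real_,
    efficiency = global_efficiency(build_network(events, roster))
  )
}

#' Pair-type discrepancy between a simulation and a target
#'
#' The total absolute difference `D` between the four pair-type counts
#' (F->F, F->NF, NF->F, NF->NF) of a model and a target; `D = 0` iff the
#' counts match exactly.
#'
#' @param counts,target Numeric vectors of the four pair-type counts,
#'   named (`n_F_F` or `F_F` style) or in the order F_F, F_NF, NF_F,
#'   NF_NF.
#' @return `D >= 0`.
#' @export
pair_type_discrepancy <- function(counts, target) {
  norm <- function(x) {
    if (!is.null(names(x))) {
      key <- sub("^n_", "", names(x))
      x <- x[match(c("F_F", "F_NF", "NF_F", "NF_NF"), key)]
    }
    unname(as.numeric(x))
  }
  a <- norm(counts); b <- norm(target)
  if (length(a) != 4 || length(b) != 4 || anyNA(a) || anyNA(b)) {
    stop("need the four pair-type counts", call. = FALSE)
  }
  sum(abs(a - b))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares the distribution of a statistic (for example, per-ant event
#' counts) between two samples by the maximum gap between their
#' empirical CDFs.
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @return A tibble `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("KS comparison needs two nonempty samples", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b))
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
                 n_a = length(sample_a), n_b = length(sample_b))
}

#' Two-sample Mann-Whitney comparison
#'
#' Rank-based comparison of the per-replicate counts of a pair type (or
#' any other statistic) between two samples. The reported `U` is for the
#' first sample; swapping samples maps `U` to `n_a * n_b - U`.
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @return A tibble `U`, `p_value`, `n_a`, `n_b`.
#' @export
mw_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("Mann-Whitney comparison needs two nonempty samples", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b, exact = FALSE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1      # complete ties: no evidence of a difference
  tibble::tibble(U = unname(wt$statistic), p_value = p,
                 n_a = length(sample_a), n_b = length(sample_b))
}

#' Z-test of an experimental mean against a simulated ensemble
#'
#' Mirrors the resampling protocol used to compare a small set of
#' experimental colonies with a large simulated ensemble: draw
#' `n_draws` (default 200) groups of `group_size` (default 5) distinct
#' replicates from the ensemble, compute each group's mean, and test the
#' experimental mean against the distribution of those group means:
#' `Z = (experimental mean - mean of group means) / SD of group means`,
#' with a two-sided normal p-value. Groups are drawn without replacement
#' within a group and independently across groups.
#'
#' @param experimental_values Per-colony experimental values (their mean
#'   is tested).
#' @param ensemble_values Per-replicate simulated values (`>=
#'   group_size`).
#' @param n_draws Number of resampled groups.
#' @param group_size Replicates per group.
#' @return A tibble `Z`, `p_value`, `experimental_mean`,
#'   `ensemble_mean`, `resampled_sd`, `n_experimental`, `n_ensemble`.
#' @export
z_compare <- function(experimental_values, ensemble_values,
                      n_draws = 200, group_size = 5) {
  if (length(ensemble_values) < group_size) {
    stop("ensemble must have at least ", group_size, " replicates", call. = FALSE)
  }
  if (length(experimental_values) == 0) {
    stop("no experimental values", call. = FALSE)
  }
  means <- vapply(seq_len(n_draws), function(i) {
    mean(sample(ensemble_values, group_size, replace = FALSE))
  }, numeric(1))
  s <- stats::sd(means)
  if (!is.finite(s) || s == 0) {
    stop("degenerate ensemble: resampled group means have zero spread",
         call. = FALSE)
  }
  z <- (mean(experimental_values) - mean(means)) / s
  tibble::tibble(Z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 experimental_mean = mean(experimental_values),
                 ensemble_mean = mean(means), resampled_sd = s,
                 n_experimental = length(experimental_values),
                 n_ensemble = length(ensemble_values))
}

#' Calibrate giving/receiving means against target statistics
#'
#' Coordinate grid search over the population means of the giving and
#' receiving maxima (per caste), minimising a weighted L1 loss between
#' simulated ensemble statistics and the targets: the mean number of
#' trophallactic events, the mean number of foragers (scaled up, since
#' a one-forager error matters more than a one-event error) and the
#' pair-type discrepancy `D`.
#'
#' Each candidate is scored with a small ensemble (`n_reps` replicates);
#' the search repeatedly sweeps each free parameter over a multiplicative
#' grid around the current best value, shrinking the grid each pass,
#' until the evaluation budget is exhausted.
#'
#' @param targets A one-row tibble (or named list) with `n_events`,
#'   `n_foragers` and pair-type counts `n_F_F`, `n_F_NF`, `n_NF_F`,
#'   `n_NF_NF` (ensemble means).
#' @param config Baseline [sim_config()]; everything except the searched
#'   means is held fixed.
#' @param search Named list of free parameters, each an entry
#'   `list(lower, upper)` with names among `theta_f`, `theta_nf`,
#'   `gamma_f`, `gamma_nf`; `NULL` entries (or omitted names) stay at the
#'   config value. An empty list scores the starting point only.
#' @param start Optional named vector of starting means (defaults to the
#'   config's regime means).
#' @param budget Maximum number of ensemble evaluations (default 40).
#' @param n_reps Replicates per evaluation (default 200).
#' @param base_seed Seed offset used for every evaluation ensemble (the
#'   same seeds are reused across candidates, which makes the loss
#'   surface smooth in the parameters).
#' @param weights Loss weights `c(events, foragers, pairs)`.
#' @return A `troph_calibration` list: `best` (named vector of fitted
#'   means), `best_loss`, `best_stats` (achieved ensemble means), `trace`
#'   (tibble of every evaluation), `converged` (`FALSE` when the budget
#'   ran out while the search still wanted to refine).
#' @export
calibrate <- function(targets, config, search, start = NULL,
                      budget = 40, n_reps = 200, base_seed = 0,
                      weights = c(events = 1, foragers = 5, pairs = 1)) {
  targets <- as.list(targets)
  target_counts <- c(targets$n_F_F, targets$n_F_NF, targets$n_NF_F, targets$n_NF_NF)
  free <- names(search)
  bad <- setdiff(free, c("theta_f", "theta_nf", "gamma_f", "gamma_nf"))
  if (length(bad)) stop("unknown search parameters: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  regime <- config$regime
  current <- c(theta_f = regime$theta_f$mean, theta_nf = regime$theta_nf$mean,
               gamma_f = regime$gamma_f$mean, gamma_nf = regime$gamma_nf$mean)
  if (!is.null(start)) current[names(start)] <- start

  with_means <- function(m) {
    mk <- function(spec, mean) trait_spec(spec$kind, mean)
    reg <- if (regime$kind == "OC") {
      caste_regime("OC", theta_nf = mk(regime$theta_nf, m[["theta_nf"]]),
                   gamma_nf = mk(regime$gamma_nf, m[["gamma_nf"]]))
    } else {
      caste_regime("TEC",
                   theta_nf = mk(regime$theta_nf, m[["theta_nf"]]),
                   gamma_nf = mk(regime$gamma_nf, m[["gamma_nf"]]),
                   theta_f = mk(regime$theta_f, m[["theta_f"]]),
                   gamma_f = mk(regime$gamma_f, m[["gamma_f"]]))
    }
    cfg <- config
    cfg$regime <- reg
    cfg
  }

  n_eval <- 0
  trace <- list()
  evaluate <- function(m) {
    n_eval <<- n_eval + 1
    cfg_m <- tryCatch(with_means(m), error = function(e) NULL)
    if (is.null(cfg_m)) {
      # candidate violates a regime constraint (e.g. theta_F <= theta_NF)
      trace[[length(trace) + 1]] <<- tibble::tibble(
        eval = n_eval, !!!as.list(m), loss = Inf,
        n_events = NA_real_, n_foragers = NA_real_, D = NA_real_)
      return(list(loss = Inf, stats = NULL))
    }
    ens <- run_ensemble(cfg_m, n_reps = n_reps, base_seed = base_seed)
    s <- ens$summaries
    counts <- colMeans(s[, c("n_F_F", "n_F_NF", "n_NF_F", "n_NF_NF")])
    loss <- weights[["events"]] * abs(mean(s$n_events) - targets$n_events) +
      weights[["foragers"]] * abs(mean(s$n_foragers) - targets$n_foragers) +
      weights[["pairs"]] * pair_type_discrepancy(counts, target_counts)
    trace[[length(trace) + 1]] <<- tibble::tibble(
      eval = n_eval, !!!as.list(m), loss = loss,
      n_events = mean(s$n_events), n_foragers = mean(s$n_foragers),
      D = pair_type_discrepancy(counts, target_counts))
    list(loss = loss,
         stats = c(n_events = mean(s$n_events), n_foragers = mean(s$n_foragers),
                   counts))
  }

  best <- evaluate(current)
  best_m <- current
  converged <- TRUE
  if (length(free) > 0) {
    span <- 1.6           # initial multiplicative half-width of the sweep
    repeat {
      improved <- FALSE
      for (p in free) {
        lo <- search[[p]]$lower %||% search[[p]][[1]]
        hi <- search[[p]]$upper %||% search[[p]][[2]]
        grid <- best_m[[p]] * c(1 / span, 1 / sqrt(span), sqrt(span), span)
        grid <- unique(pmin(pmax(grid, lo), hi))
        for (val in grid) {
          if (n_eval >= budget) break
          cand <- best_m
          cand[[p]] <- val
          r <- evaluate(cand)
          if (r$loss < best$loss) {
            best <- r; best_m <- cand; improved <- TRUE
          }
        }
        if (n_eval >= budget) break
      }
      if (n_eval >= budget) {
        if (improved || span > 1.1) converged <- FALSE
        if (!improved && span <= 1.1) converged <- TRUE
        if (converged == FALSE) warning("calibration budget exhausted; returning best so far",
                                        call. = FALSE)
        break
      }
      if (!improved) {
        if (span <= 1.1) break
        span <- sqrt(span)
      }
    }
  }
  structure(list(best = best_m, best_loss = best$loss, best_stats = best$stats,
                 trace = dplyr::bind_rows(trace), converged = converged,
                 targets = targets, n_reps = n_reps),
            class = "troph_calibration")
}

#' @export
print.troph_calibration <- function(x, ...) {
  cat("<troph_calibration> ", nrow(x$trace), " evaluations at ", x$n_reps,
      " replicates each\n", sep = "")
  cat("  fitted means:", paste(names(x$best),
                               format(x$best, digits = 4), collapse = ", "), "\n")
  cat("  loss ", format(x$best_loss, digits = 4),
      if (!x$converged) " (budget exhausted)" else "", "\n", sep = "")
  invisible(x)
}

#' @describeIn calibrate `tidy()` returns the evaluation trace.
#' @param x A `troph_calibration`.
#' @param ... Unused.
#' @export
tidy.troph_calibration <- function(x, ...) x$trace

#' @describeIn calibrate `glance()` returns the fitted means and loss.
#' @export
glance.troph_calibration <- function(x, ...) {
  tibble::tibble(!!!as.list(x$best), loss = x$best_loss,
                 n_evals = nrow(x$trace), converged = x$converged)
}

#' Compare a simulated ensemble with (synthetic) experimental colonies
#'
#' Runs the full comparison protocol between a simulated ensemble and a
#' set of per-colony experimental summaries: a Z-test of the mean event
#' count, Mann-Whitney comparisons of each pair-type count where both
#' sides provide counts, and a KS comparison of per-ant activity when
#' per-ant counts are supplied.
#'
#' @param ensemble A `troph_ensemble`.
#' @param colony_stats Tibble with one row per experimental colony and at
#'   least an `n_events` column; optional pair-type count columns
#'   `n_F_F`, ..., as from [summarize_simulation()].
#' @param activity_sim,activity_exp Optional per-ant activity count
#'   vectors for the KS comparison.
#' @return A list of tibbles: `z_events`, `mw_pair_types` (possibly
#'   empty), `ks_activity` (or `NULL`).
#' @export
compare_ensemble_experiment <- function(ensemble, colony_stats,
                                        activity_sim = NULL,
                                        activity_exp = NULL) {
  stopifnot(inherits(ensemble, "troph_ensemble"))
  s <- ensemble$summaries
  out <- list(z_events = z_compare(colony_stats$n_events, s$n_events))
  pt_cols <- intersect(c("n_F_F", "n_F_NF", "n_NF_F", "n_NF_NF"),
                       intersect(names(colony_stats), names(s)))
  out$mw_pair_types <- purrr::map_dfr(pt_cols, function(col) {
    dplyr::mutate(mw_compare(colony_stats[[col]], s[[col]]),
                  pair_type = sub("^n_", "", col), .before = 1)
  })
  out$ks_activity <- if (!is.null(activity_sim) && !is.null(activity_exp)) {
    ks_compare(activity_sim, activity_exp)
  } else NULL
  out
}
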