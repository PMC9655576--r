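test_that("scan sampling applies the duration threshold and scan instants", {
  # 4-second contact: below the strict > 5 s threshold, never recorded
  short <- tibble::tibble(donor = 1, receiver = 2, t_start = 10, t_end = 13)
  expect_equal(nrow(scan_sample(short)), 0)
  # spans the scans at 120 and 180 -> one observed event of 2 minutes
  spanning <- tibble::tibble(donor = 1, receiver = 2, t_start = 115, t_end = 185)
  obs <- scan_sample(spanning)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$first_scan_minute, 2)
  expect_equal(obs$duration_minutes, 2)
  # 10-second contact strictly between scans at 60 and 120: unobserved
  between <- tibble::tibble(donor = 1, receiver = 2, t_start = 61, t_end = 70)
  expect_equal(nrow(scan_sample(between)), 0)
  # exactly at a scan instant counts as ongoing
  at_scan <- tibble::tibble(donor = 1, receiver = 2, t_start = 60, t_end = 66)
  expect_equal(nrow(scan_sample(at_scan)), 1)
})

test_that("scan sampling matches the brute-force oracle on random logs", {
  set.seed(41)
  for (rep in 1:10) {
    n_ev <- sample(1:12, 1)
    t_start <- sample(1:900, n_ev, replace = TRUE)
    events <- tibble::tibble(
      donor = sample(1:4, n_ev, replace = TRUE),
      receiver = sample(5:8, n_ev, replace = TRUE),
      t_start = t_start,
      t_end = t_start + sample(0:200, n_ev, replace = TRUE)
    )
    got <- scan_sample(events)
    want <- oracle_scan(events)
    expect_equal(as.data.frame(got[order(got$donor, got$receiver, got$first_scan_minute), ]),
                 as.data.frame(want[order(want$donor, want$receiver, want$first_scan_minute), ]),
                 ignore_attr = TRUE)
    # contractive: never more observed than raw events
    expect_lte(nrow(got), nrow(events))
  }
})

test_that("reversed roles on consecutive scans stay separate events", {
  ev <- tibble::tibble(donor = c(1, 2), receiver = c(2, 1),
                       t_start = c(100, 160), t_end = c(130, 190))
  obs <- scan_sample(ev)
  expect_equal(nrow(obs), 2)
})

test_that("pair types partition the event log", {
  ev <- tibble::tibble(
    donor = c(1, 1, 3, 4), receiver = c(2, 3, 4, 1),
    t_start = c(5, 10, 15, 20), t_end = c(6, 11, 16, 21),
    donor_caste = c("F", "F", "NF", "NF"),
    receiver_caste = c("F", "NF", "NF", "F")
  )
  pt <- classify_pair_types(ev)
  expect_equal(pt$count, c(1L, 1L, 1L, 1L))
  expect_equal(sum(pt$count), nrow(ev))
  expect_equal(sum(pt$proportion), 1)

  # resolved from first-visit times when caste columns are absent
  fv <- c(`1` = 3, `2` = 18, `3` = NA, `4` = NA)
  pt2 <- classify_pair_types(ev[, 1:4], first_visit_times = fv)
  # at t=5 ant 2 has not yet visited: F->NF; at t=20 ant 1 is F: NF->F
  expect_equal(pt2$count[pt2$pair_type == "F_NF"], 2L)
  expect_equal(pt2$count[pt2$pair_type == "NF_NF"], 1L)
  expect_equal(pt2$count[pt2$pair_type == "NF_F"], 1L)

  all_nf <- classify_pair_types(dplyr::mutate(ev, donor_caste = "NF",
                                              receiver_caste = "NF"))
  expect_equal(all_nf$count, c(0L, 0L, 0L, 4L))
  expect_error(classify_pair_types(ev[, 1:4], first_visit_times = c(`1` = 3)),
               "missing")
})

test_that("synthetic experiments are reproducible and well-formed", {
  cfg <- tiny_config(n_ants = 15, n_steps = 900)
  a <- generate_synthetic_experiment(n_colonies = 2, config = cfg, seed = 5)
  b <- generate_synthetic_experiment(n_colonies = 2, config = cfg, seed = 5)
  expect_identical(a$events, b$events)
  expect_identical(a$workers, b$workers)
  expect_setequal(unique(a$workers$colony), 1:2)
  expect_equal(nrow(a$workers), 30)
  # observed events expand to one row per colony-minute-pair
  if (nrow(a$observed) > 0) {
    expect_equal(nrow(a$events), sum(a$observed$duration_minutes))
  }
})

test_that("experiment CSVs round-trip through the reader", {
  cfg <- tiny_config(n_ants = 15, n_steps = 900,
                     alpha = alpha_spec("delta", min_value = 0.01,
                                        forager_multiplier = 2))
  dir <- withr::local_tempdir()
  out <- generate_synthetic_experiment(n_colonies = 2, config = cfg, seed = 8,
                                       dir = dir)
  expect_true(file.exists(file.path(dir, "events.csv")))
  expect_true(file.exists(file.path(dir, "workers.csv")))
  if (nrow(out$events) > 0) {
    back <- read_experiment_events(file.path(dir, "events.csv"))
    key <- function(d) d[order(d$colony, d$donor, d$receiver,
                               d$first_scan_minute), ]
    want <- key(out$observed)
    got <- key(back)
    expect_equal(got$first_scan_minute, want$first_scan_minute)
    expect_equal(got$duration_minutes, want$duration_minutes)
  }
})

test_that("an inert colony yields an empty event table with headers", {
  regime <- caste_regime("OC", theta_nf = trait_spec("delta", 1e-12),
                         gamma_nf = trait_spec("delta", 1e-12))
  cfg <- sim_config(n_ants = 2, n_steps = 120, regime = regime,
                    alpha = alpha_spec("delta", min_value = 1e-12))
  out <- generate_synthetic_experiment(n_colonies = 1, config = cfg, seed = 1)
  expect_equal(nrow(out$events), 0)
  expect_named(out$events, c("colony", "minute", "donor", "receiver"))
  expect_equal(nrow(out$workers), 2)
  expect_false(any(out$workers$is_forager))
})
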