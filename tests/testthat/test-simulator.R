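test_that("identical config and seed reproduce bit-identical results", {
  cfg <- tiny_config()
  a <- run_simulation(cfg, seed = 11)
  b <- run_simulation(cfg, seed = 11)
  expect_identical(a$events, b$events)
  expect_identical(a$ants, b$ants)
  c <- run_simulation(cfg, seed = 12)
  expect_false(identical(a$events, c$events))
})

test_that("zero steps yield no dynamics", {
  res <- run_simulation(tiny_config(n_steps = 0), seed = 1)
  expect_equal(nrow(res$events), 0)
  expect_length(res$forager_ids, 0)
  expect_equal(res$withdrawn, 0)
})

test_that("nobody leaves when the leaving maximum is (numerically) zero", {
  cfg <- tiny_config(alpha = alpha_spec("delta", min_value = 1e-12))
  res <- run_simulation(cfg, seed = 2)
  expect_length(res$forager_ids, 0)
  # without foragers no food enters the nest, so no donor can ever act
  expect_equal(nrow(res$events), 0)
  expect_true(all(res$ants$crop == 0))
})

test_that("without donors only foragers carry food and no events occur", {
  regime <- caste_regime("OC",
                         theta_nf = trait_spec("delta", 1e-12),
                         gamma_nf = trait_spec("delta", 0.5))
  cfg <- tiny_config(regime = regime)
  res <- run_simulation(cfg, seed = 3)
  expect_equal(nrow(res$events), 0)
  nf <- is.na(res$ants$first_visit)
  expect_true(all(res$ants$crop[nf] == 0))
  expect_true(any(res$ants$crop[!nf] > 0))
})

test_that("food is conserved exactly at every timestep", {
  for (seed in 1:5) {
    res <- run_simulation(tiny_config(n_ants = 20, n_steps = 800), seed = seed)
    expect_lt(res$max_conservation_dev, 1e-8)
    expect_equal(sum(res$ants$crop), res$withdrawn, tolerance = 1e-12)
    expect_true(all(res$ants$crop >= 0))
  }
})

test_that("event amounts follow transfer_rate x duration unless truncated", {
  res <- run_simulation(tiny_config(n_ants = 25, n_steps = 1500), seed = 9)
  ev <- res$events
  expect_true(all(ev$t_end >= ev$t_start))
  expect_true(all(ev$amount >= 0))
  rate <- res$config$transfer_rate
  full <- ev$amount == rate * (ev$t_end - ev$t_start + 1)
  # truncated events (donor emptied or horizon) transfer strictly less
  expect_true(all(full | ev$amount < rate * (ev$t_end - ev$t_start + 1)))
  expect_gt(mean(full), 0.5)
})

test_that("with phi = 1 every exchange lasts exactly one timestep", {
  cfg <- tiny_config(n_ants = 25, n_steps = 1500, phi = 1)
  res <- run_simulation(cfg, seed = 4)
  ev <- res$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$t_end == ev$t_start))
  expect_true(all(ev$amount <= cfg$transfer_rate + 1e-12))
})

test_that("mean event duration approaches 1/phi for abundant crops", {
  # geometric separation: with a tiny transfer rate donors never empty
  cfg <- tiny_config(n_ants = 30, n_steps = 3000, phi = 0.25,
                     transfer_rate = 1e-4, intake_rate = 50)
  durs <- unlist(lapply(1:6, function(s) {
    ev <- run_simulation(cfg, seed = s)$events
    ev$t_end[ev$t_end < 3000] - ev$t_start[ev$t_end < 3000] + 1
  }))
  expect_gt(length(durs), 150)
  expect_lt(abs(mean(durs) - 4), 3 * sd(durs) / sqrt(length(durs)) + 0.05)
})

test_that("pairing is a matching: an ant is in at most one event at a time", {
  res <- run_simulation(tiny_config(n_ants = 30, n_steps = 2000, phi = 0.02),
                        seed = 5)
  ev <- res$events
  expect_true(all(ev$donor != ev$receiver))
  for (id in unique(c(ev$donor, ev$receiver))) {
    mine <- ev[ev$donor == id | ev$receiver == id, ]
    mine <- mine[order(mine$t_start), ]
    if (nrow(mine) > 1) {
      # an ant's next event cannot start before its previous one ended
      # (a boundary-sharing second occurs when a donor empties and the
      # freed partner pairs again within the same timestep)
      expect_true(all(mine$t_start[-1] >= mine$t_end[-nrow(mine)]))
    }
  }
})

test_that("forager status is absorbing and recorded consistently", {
  res <- run_simulation(tiny_config(), seed = 6)
  expect_setequal(res$forager_ids, res$ants$id[!is.na(res$ants$first_visit)])
  expect_true(all(res$ants$caste[res$ants$id %in% res$forager_ids] == "F"))
  expect_true(all(res$ants$caste[!res$ants$id %in% res$forager_ids] == "NF"))
  # caste labels recorded on events match promotion times
  ev <- res$events
  fv <- stats::setNames(res$ants$first_visit, res$ants$id)
  lab <- function(id, t) ifelse(!is.na(fv[as.character(id)]) &
                                  fv[as.character(id)] <= t, "F", "NF")
  expect_equal(ev$donor_caste, unname(lab(ev$donor, ev$t_start)))
  expect_equal(ev$receiver_caste, unname(lab(ev$receiver, ev$t_start)))
})

test_that("ensembles derive replicate seeds from the base seed", {
  cfg <- tiny_config()
  ens <- run_ensemble(cfg, n_reps = 3, base_seed = 100, keep_results = TRUE)
  expect_equal(ens$summaries$seed, c(101, 102, 103))
  direct <- run_simulation(cfg, seed = 102)
  expect_identical(ens$results[[2]]$events, direct$events)
  # a one-rep ensemble's summary equals the single run's summary
  one <- run_ensemble(cfg, n_reps = 1, base_seed = 101)
  expect_equal(one$summaries[, -(1:2)], summarize_simulation(direct))
})

test_that("crop trajectories are recorded at the requested cadence", {
  cfg <- tiny_config(n_ants = 8, n_steps = 300, traj_every = 50)
  res <- run_simulation(cfg, seed = 7)
  expect_equal(dim(res$crop_trajectory), c(8, 6))
  expect_equal(res$crop_trajectory[, 6], res$ants$crop)
})

test_that("invalid configurations are rejected before any stepping", {
  expect_error(sim_config(n_ants = 1), "n_ants")
  expect_error(sim_config(beta = 0), "beta and phi")
  expect_error(sim_config(phi = 1.4), "beta and phi")
  expect_error(sim_config(intake_rate = -2), "intake_rate")
  expect_error(sim_config(k = 0), "k and n")
})
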