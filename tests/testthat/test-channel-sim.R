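test_that("state-path simulation respects the aggregated chain structure", {
  m <- wt_model(k_open = 50, k_close = 50)
  p <- simulate_state_path(m, duration = 20, seed = 11)
  expect_true(all(p$dwells > 0))
  expect_equal(sum(p$dwells), 20, tolerance = 1e-10)
  expect_true(all(abs(diff(p$levels)) == 1))
  expect_true(all(p$levels >= 0 & p$levels <= 3))
  # reproducible for a fixed seed
  p2 <- simulate_state_path(m, duration = 20, seed = 11)
  expect_identical(p$levels, p2$levels)
  expect_identical(p$dwells, p2$dwells)
})

test_that("an absorbing closed state yields one dwell spanning the horizon", {
  m <- gating_model(3, k_open = 0, k_close = 10,
                    level_conductances = c(0, 42.2, 100.6, 163.7))
  p <- simulate_state_path(m, duration = 5, seed = 1)
  expect_identical(p$levels, 0L)
  expect_equal(p$dwells, 5)
})

test_that("invalid simulation parameters are rejected", {
  m <- wt_model()
  expect_error(simulate_state_path(m, duration = 0), "duration")
  expect_error(simulate_state_path(m, duration = -1), "duration")
  expect_error(gating_model(3, k_open = -1, k_close = 1,
                            level_conductances = c(0, 1, 2, 3)), "rates")
  expect_error(gating_model(3, k_open = 1, k_close = 1,
                            level_conductances = c(0, 3, 2, 1)),
               "non-decreasing")
  expect_error(gating_model(3, k_open = 1, k_close = 1,
                            level_conductances = c(1, 2, 3, 4)),
               "must be 0")
})

test_that("long-run occupancies match the binomial stationary law", {
  # N independent two-state monomers: stationary occupancy of the
  # aggregated level is Binomial(N, k_open / (k_open + k_close))
  m <- wt_model(k_open = 50, k_close = 50)
  p <- simulate_state_path(m, duration = 800, seed = 3) # ~1.2e5 dwells
  f <- state_path_occupancy(p)
  expect_equal(f, dbinom(0:3, 3, 0.5), tolerance = 0.02)
  chk <- binomial_occupancy_check(as_idealized_record(p), 3)
  expect_gt(chk$p_value, 0.01)
})

test_that("aggregated-level sojourns are exponential with the exit rate", {
  kc <- 40
  m <- wt_model(k_open = 120, k_close = kc) # p = 0.75, level 3 well visited
  p <- simulate_state_path(m, duration = 400, seed = 5)
  rec <- as_idealized_record(p)
  d3 <- dwell_summary(extract_dwells(rec, 3))
  expect_gt(d3$n, 1e4)
  # mean sojourn at the top level is 1 / (3 k_close)
  expect_equal(d3$mean, 1 / (3 * kc), tolerance = 0.05)
  # exponentiality: mean ~ sd
  expect_equal(d3$sd / d3$mean, 1, tolerance = 0.05)
})

test_that("GHK current obeys symmetry and handles the V = 0 singularity", {
  sym <- sym_k_conditions()
  expect_identical(ghk_current(0, sym), 0)
  v <- c(1e-12, 0.5, 5, 60)
  expect_equal(ghk_current(-v, sym), -ghk_current(v, sym),
               tolerance = 1e-12)
  expect_false(any(is.nan(ghk_current(c(-1e-15, 0, 1e-15), sym))))
})

test_that("GHK zero-current voltage matches the closed-form reversal", {
  cond <- bi_ionic_conditions(p_ratio = 1.21)
  root <- uniroot(function(v) ghk_current(v, cond), c(-20, 20),
                  tol = 1e-12)$root
  expect_equal(root, ghk_reversal(cond), tolerance = 1e-8)
  expect_equal(root, 4.86, tolerance = 0.01) # (RT/F) ln(1.21) at 295.65 K
})

test_that("rendered traces realise the level currents exactly without noise", {
  m <- wt_model()
  cfg <- recording_config(duration = 0.5, noise_sd = 0,
                          filter_cutoff = NA, holding_potential = 60,
                          sampling_rate = 50000)
  p <- simulate_state_path(m, duration = 0.5, seed = 21)
  tr <- render_trace(p, cfg, sym_k_conditions(), m)
  expect_length(tr$current, 25000)
  # levels (0, 42.2, 100.6, 163.7) pS at +60 mV, E_rev = 0
  expect_equal(sort(unique(tr$current)),
               wt_level_means[sort(unique(p$levels)) + 1])
})

test_that("baseline noise has the configured standard deviation", {
  m <- gating_model(3, k_open = 1e-6, k_close = 10,
                    level_conductances = c(0, 42.2, 100.6, 163.7))
  cfg <- recording_config(duration = 4, noise_sd = 0.35,
                          filter_cutoff = NA, holding_potential = 60,
                          seed = 9)
  p <- simulate_state_path(m, duration = 4, seed = 9) # stays closed
  tr <- render_trace(p, cfg, sym_k_conditions(), m)
  expect_gt(length(tr$current), 1e5)
  expect_equal(sd(tr$current), 0.35, tolerance = 0.02)
  expect_equal(mean(tr$current), 0, tolerance = 0.01)
})

test_that("the Gaussian filter attenuates but preserves plateau levels", {
  m <- wt_model(k_open = 5, k_close = 5)
  cfg <- recording_config(duration = 2, noise_sd = 0,
                          filter_cutoff = 500, holding_potential = 60)
  p <- simulate_state_path(m, duration = 2, seed = 4)
  tr <- render_trace(p, cfg, sym_k_conditions(), m)
  # away from transitions the filtered trace sits on the level currents
  expect_true(min(tr$current) > -1e-6)
  expect_true(max(tr$current) < 9.822 + 1e-6)
})

test_that("trace TSV round-trips samples and metadata", {
  m <- wt_model()
  cfg <- recording_config(duration = 0.01, noise_sd = 0.35,
                          holding_potential = 60, seed = 2)
  rec <- simulate_recording(m, cfg, sym_k_conditions(), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(rec$trace, path)
  back <- read_trace(path)
  expect_equal(back$current, rec$trace$current, tolerance = 1e-6)
  expect_equal(back$sampling_rate, 50000)
  expect_equal(back$holding_potential, 60)
})
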