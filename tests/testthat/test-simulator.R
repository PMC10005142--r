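test_that("a fixed seed reproduces scans bit-identically", {
  st <- default_sim_settings(acquisition_time = 10)
  cfg <- simulation_config(settings = st, background_mean = 10,
                           true_eta = 0.03, cal_slope = 100,
                           particle_number_concentration = 3e7,
                           size_median = 100, size_gsd = 1.4, seed = 123)
  a <- simulate_scan(cfg)
  b <- simulate_scan(cfg)
  expect_identical(a$scan$intensities, b$scan$intensities)
  expect_identical(a$truth$events, b$truth$events)
  # a different seed gives a different realization
  cfg2 <- cfg; cfg2$seed <- 124
  expect_false(identical(simulate_scan(cfg2)$scan$intensities,
                         a$scan$intensities))
})

test_that("background counts follow the configured Poisson level", {
  st <- acquisition_settings(acquisition_time = 60)  # 20,000 dwells
  cfg <- simulation_config(settings = st, background_mean = 10,
                           envelope = c(0, Inf, 0), envelope_delay = 0,
                           seed = 321)
  sim <- simulate_scan(cfg)
  expect_equal(sim$scan$n_points, 20000)
  expect_equal(nrow(sim$truth$events), 0L)
  # sample mean within 3 * sqrt(lambda / n) of lambda
  expect_lt(abs(mean(sim$scan$intensities) - 10), 3 * sqrt(10 / 20000))
  # all-dwell variance is also Poisson-like
  expect_equal(var(sim$scan$intensities), 10, tolerance = 0.1)
})

test_that("particle-free background keeps the false-call fraction low", {
  st <- acquisition_settings(acquisition_time = 60)
  cfg <- simulation_config(settings = st, background_mean = 10,
                           envelope = c(0, Inf, 0), envelope_delay = 0,
                           seed = 55)
  sim <- simulate_scan(cfg)
  w <- transient_window(1, sim$scan$n_points, st)
  thr3 <- threshold_scan(sim$scan, w, threshold_config(k_sigma = 3))
  expect_lte(thr3$n_above_dwells / sim$scan$n_points, 0.01)
})

test_that("drift and envelope shape the expected signal", {
  st <- default_sim_settings(acquisition_time = 20)
  cfg <- simulation_config(settings = st, background_mean = 100,
                           background_drift = 0.2,
                           envelope = c(0, Inf, 0), envelope_delay = 0,
                           seed = 42)
  sim <- simulate_scan(cfg)
  lam <- sim$truth$expected_background
  # 20% linear drift: the expectation gains 20% from start to end
  expect_equal(lam[length(lam)] / lam[1], 1.2, tolerance = 0.001)

  # the envelope gates both ionic signal and particle arrivals
  cfg2 <- simulation_config(settings = st, background_mean = 0,
                            envelope = c(2, 8, 4), envelope_delay = 5,
                            ionic_concentration = 10, cal_slope = 100,
                            particle_number_concentration = 5e7,
                            size_median = 100, seed = 43)
  sim2 <- simulate_scan(cfg2)
  t_ev <- sim2$truth$events$dwell * st$dwell_time
  expect_true(all(t_ev > 5))                     # nothing before the plug
  pre <- sim2$scan$intensities[seq_len(floor(5 / st$dwell_time))]
  expect_equal(sum(pre), 0)                      # dead time is dark
})

test_that("planted events with strong spikes are recalled by the pipeline", {
  st <- default_sim_settings(acquisition_time = 70)
  cfg <- simulation_config(settings = st, background_mean = 10,
                           envelope = c(0, Inf, 0), envelope_delay = 0,
                           true_eta = 0.03, cal_slope = 100,
                           particle_number_concentration = 2e7,
                           size_median = 120, size_gsd = 1.1, seed = 77)
  sim <- simulate_scan(cfg)
  # all planted spikes are far above 10x the Poisson background SD
  expect_true(all(sim$truth$events$ideal_counts > 10 * sqrt(10)))
  thr <- threshold_scan(sim$scan,
                        transient_window(1, sim$scan$n_points, st),
                        threshold_config(k_sigma = 3))
  event_dwells <- unlist(mapply(function(s, n) s:(s + n - 1),
                                thr$events$start_index, thr$events$n_dwells,
                                SIMPLIFY = FALSE))
  recall <- mean(sim$truth$events$dwell %in% event_dwells)
  expect_gte(recall, 0.95)
})

test_that("split events spread one particle over two adjacent dwells", {
  st <- default_sim_settings(acquisition_time = 70)
  cfg <- simulation_config(settings = st, background_mean = 5,
                           envelope = c(0, Inf, 0), envelope_delay = 0,
                           true_eta = 0.03, cal_slope = 100,
                           particle_number_concentration = 5e6,
                           size_median = 150, size_gsd = 1,
                           split_events = TRUE, seed = 88)
  sim <- simulate_scan(cfg)
  thr <- threshold_scan(sim$scan,
                        transient_window(1, sim$scan$n_points, st),
                        threshold_config(k_sigma = 3, gap_tolerance = 0))
  expect_gt(nrow(thr$events), 0)
  expect_true(all(thr$events$n_dwells <= 2))
  expect_gt(max(thr$events$n_dwells), 1)
})

test_that("dissolution series conserve element mass between pools", {
  st <- default_sim_settings()
  cfg <- simulation_config(settings = st, background_mean = 10,
                           true_eta = 0.03, ionic_concentration = 0.05,
                           cal_slope = 100,
                           particle_number_concentration = 5e7,
                           size_median = 100, size_gsd = 1.4, seed = 31)
  ser <- simulate_dissolution_experiment(cfg, shrink_rate = 0.5,
                                         replicates = 1,
                                         n_population = 2000)
  tot <- ser$truth$total
  expect_true(all(abs(tot - tot[1]) <= 1e-9 * tot[1]))
  # dissolution moves mass from particles to ions monotonically
  expect_true(all(diff(ser$truth$ionic) >= 0))
  expect_true(all(diff(ser$truth$particulate) <= 0))
  expect_lt(ser$truth$n_alive[length(ser$truth$n_alive)],
            ser$truth$n_alive[1])
})

test_that("zero shrink rate freezes the dissolution series", {
  st <- default_sim_settings()
  cfg <- simulation_config(settings = st, background_mean = 10,
                           true_eta = 0.03, ionic_concentration = 0.1,
                           cal_slope = 100,
                           particle_number_concentration = 5e7,
                           size_median = 100, size_gsd = 1.3, seed = 32)
  ser <- simulate_dissolution_experiment(cfg, shrink_rate = 0,
                                         timepoints = c(0, 24, 168),
                                         replicates = 1, n_population = 1000)
  expect_equal(ser$truth$ionic, rep(0.1, 3))
  expect_equal(diff(ser$truth$particulate), c(0, 0))
  expect_equal(ser$truth$n_alive, rep(1000L, 3))
})

test_that("the acidic-fluid preset dissolves fastest, buffer slowest", {
  pres <- media_presets()
  expect_gt(pres$ALF$shrink_rate, pres$GS$shrink_rate)
  expect_gt(pres$GS$shrink_rate, pres$NaHCO3$shrink_rate)
  st <- default_sim_settings()
  run <- function(medium, seed) {
    p <- pres[[medium]]
    cfg <- simulation_config(settings = st, background_mean = p$background_mean,
                             true_eta = 0.03, ionic_concentration = p$ionic0,
                             cal_slope = 100 * p$sensitivity,
                             particle_number_concentration = 5e7,
                             size_median = 100, size_gsd = 1.3, seed = seed)
    simulate_dissolution_experiment(cfg, shrink_rate = p$shrink_rate,
                                    timepoints = c(0, 8, 48, 168),
                                    replicates = 1, n_population = 1000)
  }
  alf <- run("ALF", 41)
  buf <- run("NaHCO3", 42)
  d_alf <- alf$truth$ionic[4] - alf$truth$ionic[1]
  d_buf <- buf$truth$ionic[4] - buf$truth$ionic[1]
  expect_gt(d_alf, d_buf)
})
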