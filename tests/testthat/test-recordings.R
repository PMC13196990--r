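test_that("poisson trains respect the refractory rule and the rate law", {
  tr <- poisson_trains(20, 30, seed = 2)
  expect_length(tr$trains, 20)
  for (t in tr$trains) {
    expect_true(all(diff(t) >= 0.002 - 1e-12))
    expect_true(all(t >= 0 & t < 30))
  }
  # determinism
  tr2 <- poisson_trains(20, 30, seed = 2)
  expect_identical(tr$trains, tr2$trains)
  # 5 Hz for 1000 s: count within 3 sd of 5000 before refractory deletion;
  # deletions at 5 Hz x 2 ms are ~1%, inside the same band
  tr5 <- poisson_trains(1, 1000, rate_mean = 5, rate_sd = 0, seed = 7)
  expect_lt(abs(length(tr5$trains[[1]]) - 5000), 3 * sqrt(5000) + 0.01 * 5000)
  # rates truncated below, never nonpositive
  trlow <- poisson_trains(50, 1, rate_mean = 0, rate_sd = 1, seed = 3)
  expect_true(all(trlow$rates >= 0.1))
  expect_error(poisson_trains(2, 0), "duration")
})

test_that("modality power normalization follows the stated rules", {
  set.seed(21)
  phi <- matrix(rnorm(200, sd = 4), 10, 20)
  bz <- matrix(rnorm(200, sd = 0.02), 10, 20)
  bx <- matrix(rnorm(200, sd = 0.01), 10, 20)
  by <- matrix(rnorm(200, sd = 0.005), 10, 20)
  # phi never rescaled; single magnetic modality matches phi power exactly
  n1 <- normalize_modal_power(list(phi = phi, Bz = bz))
  expect_identical(n1$scaled$phi, phi)
  expect_equal(mean(n1$scaled$Bz^2), mean(phi^2), tolerance = 1e-9)
  # multimodal: single common factor, ratios preserved, largest-power
  # component pinned to phi's power
  n3 <- normalize_modal_power(list(phi = phi, Bx = bx, By = by, Bz = bz))
  expect_equal(n3$scaled$Bx / bx, n3$scaled$Bz / bz, tolerance = 1e-12)
  expect_equal(mean(n3$scaled$Bz^2), mean(phi^2), tolerance = 1e-9)
  expect_lt(mean(n3$scaled$By^2), mean(phi^2))
  # idempotent
  n3b <- normalize_modal_power(n3$scaled)
  expect_equal(n3b$scaled$Bx, n3$scaled$Bx, tolerance = 1e-12)
  expect_equal(unname(n3b$factors["Bz"]), 1, tolerance = 1e-9)
  expect_error(normalize_modal_power(list(phi = phi, Bz = 0 * bz)),
               "zero-power")
})

test_that("assemble_recording adds templates at spike samples", {
  sens <- make_sensor_grid(3, 3, 50)
  tp <- single_cell_templates(sens, modalities = "phi",
                              morphology = make_ball_stick(100, 2, 20, 20),
                              t_grid = default_time_grid(32))
  templates <- list(tp["phi"])
  trains <- structure(
    list(trains = list(c(0.1)), rates = 5, duration = 0.3,
         refractory = 2, seed = 1),
    class = "spike_train_set")
  rec <- assemble_recording(templates, trains, noise_rms = 0)
  fs <- rec$sampling_rate
  expect_equal(fs, 32000)
  st <- floor(0.1 * fs) + 1
  seg <- rec$data[, st:(st + 31)]
  expect_equal(seg, unname(tp$phi$values))
  # everything outside the spike is silent
  expect_true(all(rec$data[, 1:(st - 1)] == 0))
  # no spikes, no noise -> all zero
  rec0 <- assemble_recording(templates,
                             structure(list(trains = list(numeric(0)),
                                            rates = 5, duration = 0.1,
                                            refractory = 2, seed = 1),
                                       class = "spike_train_set"),
                             noise_rms = 0)
  expect_true(all(rec0$data == 0))
  # noise-only recording hits the configured RMS within 2% at 1e6 samples
  recn <- assemble_recording(templates,
                             structure(list(trains = list(numeric(0)),
                                            rates = 5, duration = 3.5,
                                            refractory = 2, seed = 1),
                                       class = "spike_train_set"),
                             noise_rms = 1.5, seed = 4)
  expect_gt(length(recn$data), 1e6)
  expect_equal(sqrt(mean(recn$data^2)), 1.5, tolerance = 0.02)
  # a spike near the end is truncated and counted
  rec_tr <- assemble_recording(templates,
                               structure(list(trains = list(c(0.2995)),
                                              rates = 5, duration = 0.3,
                                              refractory = 2, seed = 1),
                                         class = "spike_train_set"),
                               noise_rms = 0)
  expect_equal(rec_tr$truncated_spikes, 1)
})

test_that("thermal noise formulas give the canonical values", {
  expect_equal(thermal_noise_rms(0, 32000), 0)
  expect_equal(thermal_noise_rms(1e5, 64000) / thermal_noise_rms(1e5, 32000),
               sqrt(2))
  expect_equal(thermal_noise_rms(1e5, 32000, 300) * 1e6, 7.28,
               tolerance = 1e-3)
  expect_equal(rescale_noise_bandwidth(3.3, 1000, 1000), 3.3)
  expect_equal(rescale_noise_bandwidth(5, 1000, 4000), 10)
  expect_equal(rescale_noise_bandwidth(7.1, 10000 - 300, 32000), 12.9,
               tolerance = 0.01)
  expect_error(rescale_noise_bandwidth(1, 0, 100), "band_from")
})

test_that("spike train matching implements TP/(TP+FP+FN)", {
  truth <- list(c(0.1, 0.2, 0.3), c(0.5))
  # perfect prediction
  perfect <- match_spike_trains(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$well_detected, 2)
  # empty prediction
  expect_equal(match_spike_trains(list(numeric(0)), truth)$accuracy, 0)
  # toy with 3 of 4 truth spikes matched and 1 false positive:
  # accuracy = 3 / (3 + 1 + 1) = 0.6
  pred <- list(c(0.1, 0.2, 0.3, 0.41))
  toy <- match_spike_trains(pred, list(c(0.1, 0.2, 0.3, 0.45)))
  expect_equal(toy$pairs$tp, 3)
  expect_equal(toy$pairs$fp, 1)
  expect_equal(toy$pairs$fn, 1)
  expect_equal(toy$accuracy, 0.6)
  expect_equal(toy$well_detected, 0)
  # tolerance is honoured (1 ms default)
  jit <- match_spike_trains(list(c(0.1004)), list(c(0.1)))
  expect_equal(jit$accuracy, 1)
  wide <- match_spike_trains(list(c(0.103)), list(c(0.1)))
  expect_equal(wide$accuracy, 0)
  expect_error(match_spike_trains(truth, truth, tolerance = 0), "tolerance")
})

test_that("recordings export to flat binary with a probe map", {
  sens <- make_sensor_grid(3, 3, 50)
  tp <- single_cell_templates(sens, modalities = c("phi", "Bz"),
                              morphology = make_ball_stick(100, 2, 20, 20),
                              t_grid = default_time_grid(16))
  trains <- poisson_trains(1, 0.05, seed = 5)
  rec <- assemble_recording(list(tp[c("phi", "Bz")]), trains,
                            noise_rms = 1, seed = 6)
  stem <- file.path(withr::local_tempdir(), "rec")
  export_recording(rec, stem, sens)
  raw <- neuromag:::.read_f32(paste0(stem, ".bin"), length(rec$data))
  expect_equal(matrix(raw, nrow(rec$data)), rec$data, tolerance = 1e-6)
  probe <- jsonlite::read_json(paste0(stem, ".probe.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(probe$channels), 18)
  expect_setequal(unique(probe$channels$modality), c("phi", "Bz"))
  truthj <- jsonlite::read_json(paste0(stem, ".truth.json"),
                                simplifyVector = TRUE)
  expect_equal(truthj$sampling_rate, 32000)
})
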