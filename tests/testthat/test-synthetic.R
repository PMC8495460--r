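test_that("kinetic class curves follow the uptake-elimination model", {
  # step limit: huge uptake rate, no elimination -> step to amplitude at onset
  step_cl <- kinetic_class(1, amplitude = 2, onset_time = 60,
                           uptake_rate = 1e6, elimination_rate = 0)
  times <- seq(0, 300, by = 15)
  y <- make_class_curve(step_cl, times)
  expect_equal(y[times < 60], rep(0, sum(times < 60)))
  expect_equal(y[times > 60], rep(2, sum(times > 60)), tolerance = 1e-12)

  # closed-form oracle: amplitude 1, onset 0, uptake 10/min, elim ln2/20 per min
  cl <- kinetic_class(1, 1, 0, 10, log(2) / 20)
  t20 <- 20 * 60
  oracle <- (1 - exp(-10 * 20)) * exp(-(log(2) / 20) * 20)
  expect_equal(make_class_curve(cl, c(0, t20))[2L], oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.5, tolerance = 1e-8)  # e^{-200} ~ 0

  # pre-onset is exactly zero; non-increasing times rejected
  expect_equal(make_class_curve(cl, c(0, 10))[1L], 1 - exp(-10 * 0))
  expect_error(make_class_curve(cl, c(10, 10)), "increasing")
  expect_error(kinetic_class(1, -1, 0, 1, 0), "amplitude")
  expect_error(kinetic_class(1, 1, 0, 0, 0), "uptake_rate")
})

test_that("simulated stacks are deterministic and truth-consistent", {
  mo <- motion_spec(breathing_amplitude = 1.5, breathing_period = 60,
                    drift_per_frame = 0.02, noise_sd = 0.1)
  a <- tiny_sim(motion = mo, seed = 11)
  b <- tiny_sim(motion = mo, seed = 11)
  expect_identical(a$icg$data, b$icg$data)
  expect_identical(a$anatomy$data, b$anatomy$data)
  expect_identical(a$truth$true_transforms, b$truth$true_transforms)
  c_ <- tiny_sim(motion = mo, seed = 12)
  expect_false(identical(a$icg$data, c_$icg$data))

  # truth curves reproduce the kinetic formula exactly
  for (cl in test_classes()) {
    expect_identical(a$truth$true_class_curves[[as.character(cl$class_id)]],
                     make_class_curve(cl, a$truth$times))
  }

  # recorded transforms match an independent re-evaluation of the motion model
  t_s <- (seq_len(16) - 1L) * 15
  expect_equal(a$truth$true_transforms[, "dy"],
               1.5 * sin(2 * pi * t_s / 60) + (seq_len(16) - 1L) * 0.02,
               tolerance = 1e-12)
  expect_equal(a$truth$true_transforms[, "dx"], (seq_len(16) - 1L) * 0.02,
               tolerance = 1e-12)
})

test_that("motion-free noiseless ICG pixels equal background plus class curve", {
  sim <- tiny_sim(motion = motion_spec(), seed = 1)
  lab <- sim$truth$class_label_image
  anat0 <- sim$anatomy$data[, , 1L]    # static, no motion, no noise
  px <- which(lab == 2L, arr.ind = TRUE)[1L, ]
  series <- sim$icg$data[px[1L], px[2L], ]
  expect_equal(series,
               anat0[px[1L], px[2L]] + sim$truth$true_class_curves[["2"]],
               tolerance = 1e-12)
  out <- which(lab == 0L, arr.ind = TRUE)[1L, ]
  expect_equal(sim$icg$data[out[1L], out[2L], ],
               rep(anat0[out[1L], out[2L]], 16), tolerance = 1e-12)
})

test_that("noise level is calibrated and every ROI pixel has one class", {
  mo <- motion_spec(noise_sd = 0.2)
  noisy <- tiny_sim(size = 48, motion = mo, seed = 5)
  clean <- tiny_sim(size = 48, motion = motion_spec(), seed = 5)
  resid <- noisy$icg$data - clean$icg$data
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 0.2) / 0.2, 0.05)

  lab <- noisy$truth$class_label_image
  expect_true(all(lab[noisy$roi] %in% c(1L, 2L)))
  expect_true(all(lab[!noisy$roi] == 0L))

  # unknown class in the layout is rejected
  expect_error(
    simulate_msot_pair(phantom_spec(24, 24, class_layout = c(1L, 9L)),
                       test_classes(), motion_spec(), n_frames = 16),
    "absent")
})

test_that("motion bookkeeping: inverting true transforms recovers the static scene", {
  mo <- motion_spec(breathing_amplitude = 2, breathing_period = 60,
                    drift_per_frame = 0.01, noise_sd = 0)
  sim <- tiny_sim(size = 48, motion = mo, seed = 2)
  static <- tiny_sim(size = 48, motion = motion_spec(), seed = 2)
  tf <- sim$truth$true_transforms
  series <- transform_series(tf[, "dy"], tf[, "dx"], reference_index = 1L)
  undone <- apply_transforms(sim$anatomy, series)
  # compare over the interior (zero-filled borders excluded)
  core <- 6:43
  err <- undone$data[core, core, ] - static$anatomy$data[core, core, ]
  rng <- diff(range(static$anatomy$data))
  expect_lt(sqrt(mean(err^2)) / rng, 0.01)
})

test_that("decay traces hit the half-life point and baseline exactly", {
  tr <- simulate_decay_trace(t_half = 20, baseline = 7, amplitude = 12,
                             injection_time = 2, times = seq(0, 45, 0.5))
  expect_equal(tr$intensity[tr$time_min == 2 + 20], 7 + 6, tolerance = 1e-12)
  expect_equal(tr$intensity[tr$time_min < 2], rep(7, sum(tr$time_min < 2)))
  expect_equal(tr$intensity[tr$time_min == 2], 7 + 12)
  expect_error(simulate_decay_trace(t_half = 0), "t_half")
  # determinism under seed
  a <- simulate_decay_trace(20, 0, 1, noise_sd = 0.1, seed = 3)
  b <- simulate_decay_trace(20, 0, 1, noise_sd = 0.1, seed = 3)
  expect_identical(a$intensity, b$intensity)
})

test_that("dose-response generator matches the 4PL definition", {
  conc <- 10^seq(0, 4, length.out = 9)
  tab <- simulate_dose_response(ic50 = 344, hill = 1.7, top = 2, bottom = 0.5,
                                concentrations = c(conc, 344))
  y <- tab$uptake
  expect_equal(y[length(y)], (2 + 0.5) / 2, tolerance = 1e-12)  # midpoint at ic50
  expect_equal(simulate_dose_response(344, 1, 1, 0, 1e-9)$uptake, 1,
               tolerance = 1e-6)   # c -> 0 gives top
  expect_equal(simulate_dose_response(344, 1, 1, 0, 1e12)$uptake, 0,
               tolerance = 1e-6)   # c -> Inf gives bottom
  expect_error(simulate_dose_response(344, concentrations = c(1, -1)),
               "positive")
})
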