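test_that("variable-cutoff low-pass matches its frequency-response contract", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  tf <- 7 / 6   # gait period giving the conventional ~6 Hz cutoff
  x <- timetable(t, list(dc = rep(1.5, length(t)),
                         slow = sin(2 * pi * 1 * t),
                         fast = sin(2 * pi * 60 * t)))
  y <- lowpass_variable_cutoff(x, tf = tf, factor = 7)
  # cutoff is factor/tf = 6 Hz exactly
  expect_equal(7 / tf, 6)
  # DC gain 1 (to filtering precision)
  expect_lt(max(abs(y$dc - 1.5)), 1e-5)
  # 1 Hz passband tone: < 1% attenuation, phase shift < 1 sample
  mid <- 1000:3000
  expect_lt(abs(1 - max(abs(y$slow[mid]))), 0.01)
  peak_win <- 1100:1400   # window holding a single crest
  ref_peak <- which.max(x$slow[peak_win])
  out_peak <- which.max(y$slow[peak_win])
  expect_lte(abs(ref_peak - out_peak), 1)
  # 60 Hz stopband tone strongly attenuated (4th-order net rolloff)
  expect_lt(max(abs(y$fast[mid])), 0.01)
  # cutoff above Nyquist rejected
  expect_error(lowpass_variable_cutoff(x, tf = 0.01, factor = 7), "Nyquist")
})

test_that("EMG processing recovers a known envelope and normalizes to 1", {
  fs <- 2000
  t <- seq(0, 3, by = 1 / fs)
  env_true <- 0.5 * (1 + sin(2 * pi * 2 * t - pi / 2))
  set.seed(9)
  carrier <- sin(2 * pi * 80 * t + cumsum(rnorm(length(t), sd = 0.1)))
  raw <- timetable(t, list(ch = env_true * carrier))
  out <- process_emg(raw, tf = 1.1)
  expect_true(all(out$ch >= 0))
  expect_equal(max(out$ch), 1)
  mid <- 2000:5500
  expect_gt(cor(out$ch[mid], env_true[mid]), 0.95)
  # all-zero channel names the offender
  zraw <- timetable(t, list(dead = rep(0, length(t))))
  expect_error(process_emg(zraw, tf = 1.1), "dead")
})

test_that("cycle resampling yields 101 inclusive samples with spline accuracy", {
  t <- seq(0, 2, by = 0.02)   # 50 Hz
  x <- timetable(t, list(ramp = 3 * t - 1, wave = sin(2 * pi * 1.3 * t)))
  y <- resample_cycle(x, window = c(0.25, 1.35))
  expect_equal(nrow(y), 101)
  expect_equal(y$time[1], 0.25)
  expect_equal(y$time[101], 1.35)
  # linear ramp exact
  expect_lt(max(abs(y$ramp - (3 * y$time - 1))), 1e-12)
  # band-limited wave within 1e-3 of the analytic values
  expect_lt(max(abs(y$wave - sin(2 * pi * 1.3 * y$time))), 1e-3)
  expect_error(resample_cycle(x, window = c(-1, 1)), "outside")
})

test_that("heel-strike detection finds rising crossings with debounce", {
  t <- seq(0, 2, by = 0.001)
  fy <- rep(0, length(t))
  fy[t > 0.30 & t < 0.80] <- 700
  fy[t > 1.30 & t < 1.80] <- 700
  hs <- detect_heel_strikes(t, fy, threshold = 20)
  expect_equal(length(hs), 2)
  expect_equal(hs, c(0.30, 1.30), tolerance = 2e-3)
  to <- detect_toe_offs(t, fy, threshold = 20)
  expect_equal(to, c(0.80, 1.80), tolerance = 2e-3)
  expect_warning(detect_heel_strikes(t, rep(0, length(t))), "no threshold")
})

test_that("MOT/STO and CSV round-trips preserve names and values", {
  t <- seq(0, 1, by = 0.01)
  x <- timetable(t, list(hip_flexion = sin(t), knee_angle = cos(t),
                         grf_y = 700 * abs(sin(t))),
                 units = c("rad", "rad", "N"))
  f1 <- tempfile(fileext = ".mot")
  write_mot(x, f1)
  y <- read_mot(f1)
  expect_equal(names(y), names(x))
  expect_lt(max(abs(y$hip_flexion - x$hip_flexion)), 1e-9)
  expect_lt(max(abs(y$grf_y - x$grf_y)), 1e-9)
  # degrees on disk for rad columns
  raw <- readLines(f1)
  first_val <- as.numeric(strsplit(raw[length(raw)], "\t")[[1]][2])
  expect_equal(first_val, sin(1) * 180 / pi, tolerance = 1e-6)
  f2 <- tempfile(fileext = ".csv")
  write_gait_csv(x, f2)
  z <- read_gait_csv(f2)
  expect_equal(names(z), names(x))
  expect_lt(max(abs(z$knee_angle - x$knee_angle)), 1e-9)
  expect_equal(attr(z, "units")[["grf_y"]], "N")
})

test_that("filter and resample approximately commute for band-limited signals", {
  fs <- 200
  t <- seq(0, 3, by = 1 / fs)
  x <- timetable(t, list(s = sin(2 * pi * 1.5 * t) + 0.3 * sin(2 * pi * 3 * t)))
  # 301-point resampling keeps the discrete filter's frequency warping
  # (a property of the sampling rate) negligible in both orders
  a <- resample_cycle(lowpass_variable_cutoff(x, tf = 1.1, factor = 7),
                      c(0.5, 1.6), n = 301)
  b <- lowpass_variable_cutoff(resample_cycle(x, c(0.5, 1.6), n = 301),
                               tf = 1.1, factor = 7)
  # interior comparison: the first/last few samples of any zero-phase
  # filtering of a finite window carry boundary-condition transients
  core <- 31:271
  rel <- sqrt(mean((a$s[core] - b$s[core])^2)) / sqrt(mean(a$s[core]^2))
  expect_lt(rel, 1e-3)
})
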