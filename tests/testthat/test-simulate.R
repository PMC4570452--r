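test_that("simulation is deterministic and subject-independent", {
  prof <- sim_profile(session_minutes = 4, mid_late_fraction = 0.25,
                      alert_minutes_mean = 2, alert_minutes_sd = 0)
  s1 <- simulate_session(prof, 2, seed = 5)
  s2 <- simulate_session(prof, 2, seed = 5)
  expect_identical(s1$eeg, s2$eeg)
  expect_identical(s1$gyro_x, s2$gyro_x)
  expect_identical(s1$minute_labels, s2$minute_labels)

  s3 <- simulate_session(prof, 3, seed = 5)
  expect_false(identical(s1$eeg, s3$eeg))
  s4 <- simulate_session(prof, 2, seed = 6)
  expect_false(identical(s1$eeg, s4$eeg))
})

test_that("sessions carry the declared structure", {
  prof <- sim_profile(session_minutes = 6, mid_late_fraction = 1 / 6,
                      alert_minutes_mean = 3, alert_minutes_sd = 1)
  s <- simulate_session(prof, 1, seed = 2)
  expect_length(s$eeg, 6 * 60 * 128)
  expect_length(s$minute_labels, 6L)
  expect_identical(sum(is.na(s$minute_labels)), 1L)
  # monotone alert -> drowsy trajectory
  lab <- s$minute_labels
  expect_true(all(diff(ifelse(is.na(lab), 2L, lab)) >= 0))
})

test_that("cohort allocates the mid/late budget exactly", {
  prof <- sim_profile(n_subjects = 3, session_minutes = 10,
                      mid_late_fraction = 0.26,
                      alert_minutes_mean = 4, alert_minutes_sd = 1)
  sessions <- simulate_cohort(prof, seed = 9)
  expect_length(sessions, 3L)
  n_mid <- sum(vapply(sessions, function(s) sum(is.na(s$minute_labels)), 0L))
  expect_identical(n_mid, as.integer(round(0.26 * 30)))
})

test_that("cohort CSV output round-trips through the readers", {
  prof <- sim_profile(n_subjects = 2, session_minutes = 3,
                      mid_late_fraction = 1 / 3,
                      alert_minutes_mean = 1, alert_minutes_sd = 0)
  dir <- file.path(tempdir(), "simcohort")
  sessions <- simulate_cohort(prof, seed = 4, out_dir = dir)
  files <- list.files(dir, "_session\\.csv$", full.names = TRUE)
  expect_length(files, 2L)
  back <- read_session(files[1])
  expect_equal(back$eeg, sessions[[1]]$eeg, tolerance = 1e-9)
  expect_identical(back$minute_labels, sessions[[1]]$minute_labels)
})

test_that("degenerate profiles are rejected", {
  expect_error(sim_profile(rbp_alert = c(theta = -1, alpha = 60, beta = 41)),
               "positive percentages")
  expect_error(sim_profile(mp_alert = 0), "positive")
  expect_error(sim_profile(burst_rate = 20, burst_duration = c(2, 2)),
               "half the drowsy time")
  # targets whose leakage-corrected spectral solution goes negative
  p <- sim_profile(rbp_alert = c(theta = 0.5, alpha = 99, beta = 0.5),
                   session_minutes = 2, mid_late_fraction = 0,
                   alert_minutes_mean = 2, alert_minutes_sd = 0)
  expect_error(simulate_session(p, 1, 1), "no non-negative spectral")
})

test_that("indistinguishable states yield chance-level movement power", {
  prof0 <- sim_profile(n_subjects = 4, session_minutes = 30,
                       rbp_drowsy = c(theta = 18.2, alpha = 37.9,
                                      beta = 38.6),
                       mp_drowsy = 74.1, burst_rate = 0,
                       mid_late_fraction = 0,
                       alert_minutes_mean = 15, alert_minutes_sd = 2)
  u <- usable_windows(extract_cohort_features(simulate_cohort(prof0,
                                                              seed = 3),
                                              quiet = TRUE))
  r <- roc_area(u$mp, u$label)
  expect_lt(abs(r$raw_auc - 0.5), 0.05)
})

test_that("generated EEG stays inside the physiological bound", {
  for (s in default_cohort())
    expect_lt(max(abs(s$eeg)), 200)
})
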