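test_that("generated sessions have the contracted shape and are deterministic", {
  p <- regime_params("rhythmic", duration_s = 20, osc_freq_hz = 2.5)
  s <- generate_session("s01", "T1", "rattle", p, seed = 1)
  expect_equal(nrow(s), 4 * 20 * 60)
  expect_setequal(unique(s$limb), c("left_arm", "right_arm", "left_leg",
                                    "right_leg"))
  expect_equal(dplyr::count(s, limb)$n, rep(1200, 4))
  expect_identical(s, generate_session("s01", "T1", "rattle", p, seed = 1))
  expect_false(identical(s$ax, generate_session("s01", "T1", "rattle", p,
                                                seed = 2)$ax))
})

test_that("a 5-minute rattle session at 60 Hz has 18,000 samples per limb", {
  p <- regime_params("rhythmic", duration_s = 300)
  s <- generate_session("s01", "T1", "rattle", p, seed = 3)
  expect_equal(dplyr::count(s, limb)$n, rep(18000, 4))
})

test_that("rhythmic limb magnitudes peak at the oscillation frequency", {
  p <- regime_params("rhythmic", duration_s = 50, osc_freq_hz = 2.5,
                     noise_sd = 0.05, regularity = 0.9)
  s <- generate_session("s01", "T1", "rattle", p, seed = 1)
  for (l in unique(s$limb)) {
    df <- s[s$limb == l, ]
    mag <- sqrt(df$ax^2 + df$ay^2 + df$az^2)
    sp <- stats::spec.pgram(mag, plot = FALSE, taper = 0, detrend = TRUE)
    peak_hz <- sp$freq[which.max(sp$spec)] * 60
    expect_lt(abs(peak_hz - 2.5), 0.2)
  }
})

test_that("invalid regime parameters are rejected", {
  expect_error(regime_params("rhythmic", duration_s = -1), "positive")
  expect_error(regime_params("rhythmic", coupling = 1.5), "coupling")
  expect_error(regime_params("rhythmic", regularity = -0.1), "regularity")
  p <- regime_params("rhythmic", duration_s = 10, osc_freq_hz = 40)
  expect_error(generate_session("s", "T1", "rattle", p, seed = 1), "Nyquist")
})

test_that("rhythmic sessions are more autocorrelated at the oscillation lag
           than unstructured ones", {
  lag <- round(60 / 2.5)
  wins <- vapply(1:20, function(seed) {
    sr <- tiny_session(seed, regime = "rhythmic")
    su <- tiny_session(seed, regime = "unstructured")
    ac <- function(s) {
      df <- s[s$limb == "left_arm", ]
      mag <- sqrt(df$ax^2 + df$ay^2 + df$az^2)
      stats::acf(mag, lag.max = lag, plot = FALSE)$acf[lag + 1]
    }
    ac(sr) > ac(su)
  }, logical(1))
  expect_true(all(wins))
})

test_that("missingness injection hits the target rate and leaves values intact", {
  p <- regime_params("rhythmic", duration_s = 300)
  s <- generate_session("s01", "T1", "rattle", p, seed = 5)
  expect_identical(inject_missing(s, 0, seed = 1), s)
  sm <- inject_missing(s, 0.101, mean_gap = 5, seed = 7)
  fr <- mean(is.na(sm$ax))
  expect_gte(fr, 0.091)
  expect_lte(fr, 0.111)
  # observed samples untouched, edges never removed
  ok <- !is.na(sm$ax)
  expect_identical(sm$ax[ok], s$ax[ok])
  for (l in unique(s$limb)) {
    d <- sm[sm$limb == l, ]
    expect_false(is.na(d$ax[1]) || is.na(d$ax[nrow(d)]))
  }
  # half-rate, single-sample gaps
  sh <- inject_missing(s, 0.5, mean_gap = 1, seed = 2)
  expect_lt(abs(mean(is.na(sh$ax)) - 0.5), 0.01)
  expect_error(inject_missing(s, 1.2), "missing_rate")
})

test_that("cohort generation follows the design counts and is deterministic", {
  d <- cohort_design(n_per_visit = c(19, 21, 26, 17), rattle_s = 2,
                     freeplay_s = 2, missing_rate = 0, seed = 9)
  co <- generate_cohort(d)
  cells <- dplyr::distinct(co, subject, visit, task)
  expect_equal(nrow(cells), 2 * (19 + 21 + 26 + 17))
  expect_equal(dplyr::count(dplyr::distinct(co, subject, visit), visit)$n,
               c(19, 21, 26, 17))
  co2 <- generate_cohort(d)
  expect_identical(as.data.frame(co), as.data.frame(co2))

  d1 <- cohort_design(n_per_visit = c(1, 0, 0, 0), rattle_s = 2,
                      freeplay_s = 2, missing_rate = 0)
  co1 <- generate_cohort(d1)
  cells1 <- dplyr::distinct(co1, subject, visit, task)
  expect_equal(nrow(cells1), 2)
  expect_true(all(cells1$visit == "T1"))
  expect_error(generate_cohort(cohort_design(n_per_visit = c(0, 0, 0, 0))),
               "empty")
})
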