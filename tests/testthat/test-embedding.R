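test_that("binned mutual information matches an independent oracle", {
  set.seed(21)
  x <- rnorm(400)
  y <- 0.6 * x + 0.8 * rnorm(400)
  expect_equal(limbrqa:::mutual_information(x, y, 10), oracle_mi(x, y, 10),
               tolerance = 1e-12)
  # AMI at lag 0 bounds the curve
  tau <- suppressWarnings(ami_delay(matrix(rnorm(600), ncol = 1),
                                    max_lag = 20))
  curve <- attr(tau, "ami")
  expect_true(all(curve[-1] <= curve[1] + 1e-12))
})

test_that("AMI delay finds the quarter period of noisy oscillations", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- sine_channels(2000, period = 40, d = 4, noise = 0.2,
                       phases = runif(4, 0, 2 * pi))
    tau <- suppressWarnings(ami_delay(x, max_lag = 30))
    abs(as.integer(tau) - 10) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("AMI delay on iid noise sits at the noise floor immediately", {
  taus <- vapply(1:40, function(seed) {
    set.seed(seed)
    tau <- suppressWarnings(ami_delay(matrix(rnorm(4 * 2000), ncol = 4),
                                      max_lag = 20))
    curve <- attr(tau, "ami")
    expect_lt(curve[2], curve[1] / 10)      # lag 1 already at the floor
    expect_lt(diff(range(curve[-1])), 0.05) # and the floor is flat
    as.integer(tau)
  }, integer(1))
  expect_lte(median(taus), 2)
  expect_in(as.integer(names(which.max(table(taus)))), 1:2)
  expect_warning(tau1 <- ami_delay(matrix(rnorm(500), ncol = 1), max_lag = 1),
                 "local minimum")
  expect_equal(as.integer(tau1), 1L)
  expect_true(attr(tau1, "no_local_minimum"))
})

test_that("false nearest neighbours find the dimension of canonical systems", {
  # a noiseless single harmonic lives on a circle: two dimensions
  x <- sine_channels(1500, period = 40, d = 1)
  m <- fnn_dimension(x, tau = 10, max_dim = 6)
  expect_equal(as.integer(m), 2L)
  # iid noise never plateaus
  set.seed(2)
  expect_warning(mn <- fnn_dimension(matrix(rnorm(1000), ncol = 1), tau = 1,
                                     max_dim = 8), "never fell")
  expect_equal(as.integer(mn), 8L)
  expect_true(attr(mn, "no_plateau"))
})

test_that("false nearest neighbours recover the Lorenz attractor dimension", {
  lorenz <- function(t, y, p) {
    list(c(10 * (y[2] - y[1]), y[1] * (28 - y[3]) - y[2],
           y[1] * y[2] - 8 / 3 * y[3]))
  }
  out <- deSolve::ode(c(1, 1, 20), seq(0, 60, by = 0.03), lorenz, NULL)
  x <- matrix(out[-(1:500), 2], ncol = 1)  # x coordinate, transient dropped
  tau <- suppressWarnings(as.integer(ami_delay(x, max_lag = 40)))
  m <- suppressWarnings(as.integer(fnn_dimension(x, tau = tau, max_dim = 8)))
  expect_gte(m, 2L)
  expect_lte(m, 4L)
})

test_that("multidimensional embedding has the contracted geometry", {
  x <- matrix(rnorm(400), ncol = 4)
  st <- embed_multidim(x, tau = 2, m = 3)
  expect_equal(dim(st), c(96, 12))
  expect_identical(embed_multidim(x, tau = 3, m = 1), structure(
    x, tau = 3L, m = 1L, channels = colnames(x)))
  # the lag-0 columns recover the original series
  lag0 <- st[, seq(1, 12, by = 3)]
  expect_equal(lag0, x[1:96, ])
  # the operating-point shape used for these signals: delay 1, dimension 14
  big <- embed_multidim(matrix(rnorm(3000 * 4), ncol = 4), tau = 1, m = 14)
  expect_equal(dim(big), c(2987, 56))
  expect_error(embed_multidim(matrix(rnorm(20), ncol = 4), 3, 3), "short")
})

test_that("radius calibration hits the target recurrence rate", {
  set.seed(31)
  st <- matrix(rnorm(400 * 4), ncol = 4)
  eps <- calibrate_radius(st, target_rr = 5)
  expect_lte(abs(attr(eps, "achieved_rr") - 5), 0.1)
  # recurrence rate is monotone in the radius
  rrs <- vapply(seq(0.5, 4, by = 0.5), function(e)
    rqa_measures(st, e)$rr, numeric(1))
  expect_true(all(diff(rrs) >= 0))
  # the maximum pairwise distance recurs everything
  expect_equal(rqa_measures(st, limbrqa:::max_pair_dist(st))$rr, 100)
  # all-identical states cannot be calibrated
  expect_error(calibrate_radius(matrix(1, 50, 4), 5), "degenerate")
})

test_that("embedding parameters are anchored on the earliest visit per subject", {
  sessions <- dplyr::bind_rows(
    tiny_session(1, duration_s = 10, subject = "a", visit = "T1"),
    tiny_session(2, duration_s = 10, subject = "a", visit = "T3"),
    tiny_session(3, duration_s = 10, subject = "b", visit = "T2"),
    tiny_session(4, duration_s = 10, subject = "b", visit = "T4"))
  pars <- fix_params_per_subject(sessions, tau = 1, m = 3)
  expect_equal(nrow(pars), 2)
  expect_equal(pars$anchor_visit[pars$subject == "a"], "T1")
  expect_equal(pars$anchor_visit[pars$subject == "b"], "T2")
  expect_false(pars$epsilon[1] == pars$epsilon[2])
  # anchored parameters are what the earliest visit alone would give
  a1 <- preprocess_session(sessions[sessions$subject == "a" &
                                      sessions$visit == "T1", ])
  eps_a <- calibrate_radius(embed_multidim(a1, 1, 3), 5)
  expect_equal(pars$epsilon[pars$subject == "a"], as.numeric(eps_a))
})
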