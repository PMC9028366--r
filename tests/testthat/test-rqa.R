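test_that("the all-recurrent 5x5 plot reproduces the hand enumeration", {
  # identical states: every pair recurs; lmin = 2, theiler = 1
  rp <- recurrence_plot(matrix(0, 5, 2), epsilon = 1)
  expect_true(all(rp$matrix == 1))
  h <- diagonal_histogram(rp)
  expect_equal(h$length, c(2L, 3L, 4L))
  expect_equal(h$count, c(2L, 2L, 2L))
  m <- compute_measures(rp)
  expect_equal(m$rr, 100)
  expect_equal(m$ml, 3)
  expect_equal(m$ent, log(3))
  # streaming route agrees exactly
  expect_equal(rqa_measures(matrix(0, 5, 2), 1), m)
})

test_that("degenerate plots follow the empty-histogram conventions", {
  # distinct states, radius below the smallest pair distance: identity only
  st <- matrix(seq(0, 40, by = 10), ncol = 1)
  rp <- recurrence_plot(st, epsilon = 1)
  expect_true(all(rp$matrix == diag(5)))
  expect_equal(nrow(diagonal_histogram(rp)), 0)
  m <- compute_measures(rp)
  expect_equal(unlist(m), c(rr = 0, ent = 0, ml = 0, n_lines = 0))
  # a single off-diagonal run of length 1 stays below lmin
  r1 <- diag(6)
  r1[1, 3] <- r1[3, 1] <- 1
  expect_equal(nrow(diagonal_histogram(r1, rqa_config())), 0)
  # equal-length lines carry zero entropy
  r2 <- diag(6)
  for (i in 1:2) { r2[i, i + 4] <- 1; r2[i + 4, i] <- 1 }
  m2 <- compute_measures(r2, rqa_config())
  expect_equal(m2$ent, 0)
  expect_equal(m2$ml, 2)
})

test_that("streaming measures equal the full-matrix route and the R oracle", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(20:120, 1)
    st <- matrix(rnorm(n * 3), ncol = 3)
    eps <- runif(1, 0.5, 2.5)
    a <- rqa_measures(st, eps)
    b <- compute_measures(recurrence_plot(st, eps))
    o <- oracle_measures(st, eps)
    expect_identical(a$rr, b$rr)
    expect_identical(a$ent, b$ent)
    expect_identical(a$ml, b$ml)
    expect_identical(a$n_lines, b$n_lines)
    expect_equal(a$rr, o$rr)
    expect_equal(a$ent, o$ent)
    expect_equal(a$ml, o$ml)
    expect_equal(a$n_lines, o$n_lines)
  }
})

test_that("the recurrence matrix matches the brute-force double loop", {
  set.seed(43)
  st <- matrix(rnorm(60 * 4), ncol = 4)
  eps <- 1.8
  rp <- recurrence_plot(st, eps)
  expect_equal(rp$matrix, oracle_recurrence_matrix(st, eps))
  expect_true(isSymmetric(rp$matrix))
  expect_true(all(diag(rp$matrix) == 1))
})

test_that("measures are invariant to channel relabelling and time reversal", {
  set.seed(47)
  st <- matrix(rnorm(80 * 4), ncol = 4)
  eps <- 1.5
  base <- rqa_measures(st, eps)
  perm <- rqa_measures(st[, c(3, 1, 4, 2)], eps)
  expect_equal(base, perm)
  rev <- rqa_measures(st[nrow(st):1, ], eps)
  expect_equal(base, rev)
})

test_that("periodic states grow long diagonals; shuffling collapses them", {
  seps <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- sine_channels(400, period = 40, d = 2, noise = 0.05,
                       phases = runif(2, 0, 2 * pi))
    st <- embed_multidim(x, tau = 10, m = 2)
    eps <- calibrate_radius(st, 5)
    ml_obs <- rqa_measures(st, eps)$ml
    xs <- apply(x, 2, sample)
    ml_shuf <- rqa_measures(embed_multidim(xs, tau = 10, m = 2), eps)$ml
    ml_obs > ml_shuf
  }, logical(1))
  expect_true(all(seps))
})

test_that("entropy log base and theiler conventions are honoured", {
  st <- matrix(0, 5, 2)
  m2 <- rqa_measures(st, 1, rqa_config(log_base = 2))
  expect_equal(m2$ent, log2(3))
  # theiler = 0 counts the main diagonal too
  m0 <- rqa_measures(st, 1, rqa_config(theiler = 0))
  expect_equal(m0$rr, 100)
  expect_equal(compute_measures(recurrence_plot(st, 1,
                                                rqa_config(theiler = 0)),
                                rqa_config(theiler = 0)), m0)
  expect_error(rqa_config(lmin = 1), "lmin")
})
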