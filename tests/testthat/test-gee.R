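# One independent observation per subject: the GEE collapses to OLS with the
# HC0 sandwich, which `lm` + sandwich::vcovHC provide as an oracle.
test_that("with one observation per cluster the fit equals robust OLS", {
  set.seed(14)
  tb <- tidyr::expand_grid(visit = paste0("T", 1:4),
                           task = c("rattle", "freeplay"))
  tb <- tb[rep(1:8, each = 5), ]
  tb$subject <- sprintf("s%02d", seq_len(nrow(tb)))
  tb$ent <- rnorm(nrow(tb), 5, 0.5)
  fit <- fit_gee(tb, "ent", vcov = "robust", test = "chisq")
  d <- as.data.frame(tb)
  d$task <- factor(d$task, levels = c("rattle", "freeplay"))
  d$visit <- factor(d$visit)
  ols <- lm(ent ~ task * visit, d,
            contrasts = list(task = "contr.sum", visit = "contr.sum"))
  expect_equal(unname(fit$coefficients), unname(coef(ols)))
  expect_equal(unname(fit$vcov),
               unname(sandwich::vcovHC(ols, type = "HC0")),
               tolerance = 1e-8)
})

test_that("independence working correlation reproduces least squares", {
  mt <- simulate_measure_table(n_per_visit = c(8, 8, 8, 8), seed = 7)
  fit <- fit_gee(mt, "ent", corstr = "independence")
  d <- as.data.frame(mt)
  d$task <- factor(d$task, levels = c("rattle", "freeplay"))
  d$visit <- factor(d$visit)
  ols <- lm(ent ~ task * visit, d,
            contrasts = list(task = "contr.sum", visit = "contr.sum"))
  expect_equal(unname(fit$coefficients), unname(coef(ols)))
  expect_equal(fit$alpha, 0)
})

test_that("Wald tests carry the factorial degrees of freedom", {
  mt <- simulate_measure_table(seed = 11)
  fit <- fit_gee(mt, "ent")
  w <- wald_tests(fit)
  expect_equal(w$term, c("task", "visit", "task:visit"))
  expect_equal(w$df, c(1L, 3L, 3L))
  expect_true(all(w$p.value >= 0 & w$p.value <= 1))
  expect_equal(fit$n_obs, 166L)
  expect_equal(fit$n_clusters, 26L)
  expect_gt(fit$alpha, 0)  # the shared random intercept is picked up
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_clusters, 26L)
})

test_that("subjects with missing visits are retained, not dropped", {
  mt <- simulate_measure_table(seed = 12)
  full <- fit_gee(mt, "ent")
  # remove one visit of one subject: the subject must stay in the fit
  drop_one <- mt[!(mt$subject == "s01" & mt$visit == "T2"), ]
  partial <- fit_gee(drop_one, "ent")
  expect_equal(partial$n_clusters, full$n_clusters)
  expect_equal(partial$n_obs, full$n_obs - 2L)
  expect_false(isTRUE(all.equal(partial$coefficients, full$coefficients)))
  # remove the subject entirely: the cluster count drops
  drop_sub <- mt[mt$subject != "s01", ]
  expect_equal(fit_gee(drop_sub, "ent")$n_clusters, full$n_clusters - 1L)
})

test_that("degenerate designs are rejected with informative errors", {
  mt <- simulate_measure_table(seed = 13)
  expect_error(fit_gee(mt[mt$task == "rattle", ], "ent"), "task")
  expect_error(fit_gee(mt[mt$subject == "s01", ], "ent"), "subject")
  expect_error(fit_gee(mt[mt$visit == "T1", ], "ent"), "visit")
  expect_error(fit_gee(dplyr::select(mt, -"ent"), "ent"), "ent")
})

test_that("Bonferroni adjustment multiplies by the family size and caps at 1", {
  mt <- simulate_measure_table(seed = 15)
  fit <- fit_gee(mt, "ent")
  ct <- bonferroni_pairwise(fit)
  expect_equal(nrow(ct), 28)
  expect_equal(ct$adj.p.value, pmin(1, 28 * ct$p.value))
  expect_true(all(ct$adj.p.value >= ct$p.value))
  expect_true(all(diff(ct$adj.p.value[order(ct$p.value)]) >= -1e-12))
  tw <- bonferroni_pairwise(fit, family = "task_within_visit")
  expect_equal(nrow(tw), 4)
  expect_equal(tw$adj.p.value, pmin(1, 4 * tw$p.value))
})

test_that("an empty task-by-visit cell is flagged non-estimable, not dropped", {
  mt <- simulate_measure_table(seed = 16)
  mt <- mt[!(mt$task == "rattle" & mt$visit == "T4"), ]
  fit <- fit_gee(mt, "ent")
  expect_false(fit$cells$observed[fit$cells$task == "rattle" &
                                    fit$cells$visit == "T4"])
  ct <- bonferroni_pairwise(fit)
  expect_equal(nrow(ct), 28)  # nothing silently dropped
  bad <- ct[!ct$estimable, ]
  expect_equal(nrow(bad), 7)  # all pairs touching the empty cell
  expect_true(all(is.na(bad$estimate)))
  # the interaction loses one column to aliasing
  expect_equal(wald_tests(fit)$df, c(1L, 3L, 2L))
})

test_that("the default small-sample inference is calibrated under the null", {
  # no task effect, no visit effect: the interaction should reject at ~5%
  null_params <- measure_cell_defaults(null = TRUE)
  set.seed(17)
  seeds <- sample.int(2^31 - 2, 60)
  p <- vapply(seeds, function(s) {
    mt <- simulate_measure_table(cell_params = null_params, seed = s)
    wald_tests(fit_gee(mt, "ent"))$p.value[3]
  }, numeric(1))
  expect_lt(mean(p < 0.05), 0.20)  # coarse guard; the 500-replicate
                                   # calibration lives in the acceptance suite
})
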