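#' Fit a marginal (GEE) task-by-visit model to a recurrence measure
#'
#' Fits the marginal linear model `measure ~ task * visit` (Gaussian family,
#' identity link) to a long measure table by generalized estimating
#' equations: within-subject dependence is absorbed by a working
#' correlation (exchangeable by default) and inference uses robust
#' (sandwich) standard errors, so subjects with missing visits contribute
#' their remaining rows. Factors are coded with sum-to-zero contrasts, so
#' the Wald chi-square test of each term block is the Type-III test of that
#' term: task on 1 df, visit on `(levels - 1)` df, and their interaction on
#' the product.
#'
#' With few clusters the plain sandwich estimator is anti-conservative, so
#' the default applies the Mancl–DeRouen bias correction
#' (`vcov = "bias-reduced"`, which inflates each cluster's residuals by
#' `(I - H_i)^{-1}`); `vcov = "robust"` gives the uncorrected sandwich,
#' which in the degenerate one-row-per-subject case coincides exactly with
#' the HC0 heteroscedasticity-robust covariance of ordinary least squares.
#' For the same reason the default reference distribution for the term
#' tests is the small-sample F: the Wald statistic divided by its df is
#' referred to `F(df, m - p)` with `m` clusters and `p` coefficients
#' (`test = "f"`), and pairwise contrasts use the t distribution on
#' `m - p` df; `test = "chisq"` gives the asymptotic chi-square/normal
#' reference that large-sample GEE software reports. The Wald chi-square
#' statistics themselves are identical under either choice.
#'
#' @param table Measure table: tibble with columns `subject`, `visit`,
#'   `task` and the response; one row per (subject, visit, task).
#' @param response Name of the measure column (e.g. `"ent"`).
#' @param corstr Working correlation: `"exchangeable"` (default),
#'   `"independence"` or `"ar1"` (lag-1 within the subject's row order).
#' @param vcov Sandwich flavour, `"bias-reduced"` or `"robust"`.
#' @param test Reference distribution for term tests and contrasts:
#'   `"f"` (small-sample default) or `"chisq"` (asymptotic).
#' @param max_iter,tol Fisher-scoring controls.
#' @return Object of class `"limb_gee"`; see [wald_tests()],
#'   [bonferroni_pairwise()], [tidy.limb_gee()], [glance.limb_gee()].
#' @export
fit_gee <- function(table, response, corstr = c("exchangeable",
                                                "independence", "ar1"),
                    vcov = c("bias-reduced", "robust"),
                    test = c("f", "chisq"),
                    max_iter = 50, tol = 1e-8) {
  corstr <- match.arg(corstr)
  vcov <- match.arg(vcov)
  test <- match.arg(test)
  need <- c("subject", "visit", "task", response)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("measure table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(table[stats::complete.cases(table[, need]), need])
  if (length(unique(df$subject)) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  if (length(unique(df$task)) < 2)
    stop("both tasks must be present (single-level factor is rank deficient)",
         call. = FALSE)
  if (length(unique(df$visit)) < 2)
    stop("need at least 2 visit levels", call. = FALSE)
  df$task <- factor(df$task, levels = intersect(TASKS, unique(df$task)))
  df$visit <- factor(df$visit, levels = intersect(VISITS, unique(df$visit)))
  df <- df[order(df$subject, df$visit, df$task), ]
  y <- df[[response]]
  contr <- list(task = "contr.sum", visit = "contr.sum")
  mf <- stats::model.frame(~ task * visit, df)
  X <- model.matrix(~ task * visit, mf, contrasts.arg = contr)
  assign <- attr(X, "assign")
  term_labels <- attr(terms(~ task * visit), "term.labels")
  # empty task-by-visit cells leave the saturated model rank deficient;
  # drop aliased columns (pivoted QR) so the observed cells stay estimable
  qrX <- qr(X)
  kept_cols <- seq_len(ncol(X))
  if (qrX$rank < ncol(X)) {
    kept_cols <- sort(qrX$pivot[seq_len(qrX$rank)])
    X <- X[, kept_cols, drop = FALSE]
    assign <- assign[kept_cols]
  }
  p <- ncol(X)
  cl <- split(seq_len(nrow(df)), df$subject)
  cl <- cl[lengths(cl) > 0]

  beta <- qr.solve(X, y)
  alpha <- 0
  phi <- 1
  for (iter in seq_len(max_iter)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / (nrow(X) - p)
    alpha <- estimate_alpha(r, cl, phi, p, corstr)
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (idx in cl) {
      Xi <- X[idx, , drop = FALSE]
      Ri_inv <- working_corr_inv(length(idx), alpha, corstr)
      W <- crossprod(Xi, Ri_inv)
      A <- A + W %*% Xi
      b <- b + W %*% y[idx]
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta <- drop(beta)
  names(beta) <- colnames(X)

  # sandwich covariance: A^-1 B A^-1 (phi cancels between A and B)
  r <- y - X %*% beta
  A <- matrix(0, p, p)
  for (idx in cl) {
    Xi <- X[idx, , drop = FALSE]
    Ri_inv <- working_corr_inv(length(idx), alpha, corstr)
    A <- A + crossprod(Xi, Ri_inv) %*% Xi
  }
  A_inv <- solve(A)
  B <- matrix(0, p, p)
  for (idx in cl) {
    Xi <- X[idx, , drop = FALSE]
    Ri_inv <- working_corr_inv(length(idx), alpha, corstr)
    ri <- r[idx]
    if (vcov == "bias-reduced") {
      Hi <- Xi %*% A_inv %*% crossprod(Xi, Ri_inv)
      ri <- solve(diag(length(idx)) - Hi, ri)
    }
    u <- crossprod(Xi, Ri_inv %*% ri)
    B <- B + tcrossprod(u)
  }
  V <- A_inv %*% B %*% A_inv

  denom_df <- max(length(cl) - p, 1)
  wald <- purrr::map_dfr(seq_along(term_labels), function(k) {
    sel <- which(assign == k)
    if (length(sel) == 0)
      return(tibble::tibble(term = term_labels[k], chisq = NA_real_,
                            df = 0L, p.value = NA_real_))
    bk <- beta[sel]
    W <- drop(crossprod(bk, solve(V[sel, sel, drop = FALSE], bk)))
    dfk <- length(sel)
    pv <- if (test == "f") {
      stats::pf(W / dfk, dfk, denom_df, lower.tail = FALSE)
    } else {
      pchisq(W, dfk, lower.tail = FALSE)
    }
    tibble::tibble(term = term_labels[k], chisq = W, df = dfk, p.value = pv)
  })

  grid <- expand.grid(task = levels(df$task), visit = levels(df$visit),
                      KEEP.OUT.ATTRS = FALSE)
  X0 <- model.matrix(~ task * visit, grid,
                     contrasts.arg = contr)[, kept_cols, drop = FALSE]
  observed <- dplyr::distinct(df, .data$task, .data$visit)
  grid$observed <- interaction(grid$task, grid$visit) %in%
    interaction(observed$task, observed$visit)
  cell_cov <- X0 %*% V %*% t(X0)
  cells <- tibble::tibble(task = as.character(grid$task),
                          visit = as.character(grid$visit),
                          estimate = ifelse(grid$observed, drop(X0 %*% beta),
                                            NA_real_),
                          std.error = ifelse(grid$observed,
                                             sqrt(diag(cell_cov)), NA_real_),
                          observed = grid$observed)

  structure(list(response = response, coefficients = beta, vcov = V,
                 alpha = alpha, scale = phi, corstr = corstr,
                 vcov_type = vcov, test = test, denom_df = denom_df,
                 wald = wald, cells = cells,
                 cell_cov = cell_cov, n_obs = nrow(df),
                 n_clusters = length(cl), iterations = iter,
                 levels = list(task = levels(df$task),
                               visit = levels(df$visit))),
            class = "limb_gee")
}

# Moment estimator of the working-correlation parameter.
estimate_alpha <- function(r, cl, phi, p, corstr) {
  if (corstr == "independence") return(0)
  e <- r / sqrt(phi)
  num <- 0; den <- 0
  for (idx in cl) {
    ei <- e[idx]; ni <- length(ei)
    if (ni < 2) next
    if (corstr == "exchangeable") {
      num <- num + (sum(ei)^2 - sum(ei^2)) / 2
      den <- den + ni * (ni - 1) / 2
    } else {  # ar1: lag-1 products
      num <- num + sum(ei[-ni] * ei[-1])
      den <- den + ni - 1
    }
  }
  a <- if (den - p > 0) num / (den - p) else num / max(den, 1)
  max(min(a, 0.99), -0.49)
}

# Inverse working correlation matrix for a cluster of size n.
working_corr_inv <- function(n, alpha, corstr) {
  if (corstr == "independence" || n == 1 || alpha == 0) return(diag(n))
  if (corstr == "exchangeable") {
    # ((1-a)I + aJ)^-1 = (I - a/(1+(n-1)a) J) / (1-a)
    (diag(n) - matrix(alpha / (1 + (n - 1) * alpha), n, n)) / (1 - alpha)
  } else {
    R <- alpha^abs(outer(seq_len(n), seq_len(n), `-`))
    solve(R)
  }
}

#' Wald term tests of a fitted marginal model
#' @param fit A `limb_gee` object.
#' @return Tibble: `term`, `chisq`, `df`, `p.value`.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "limb_gee"))
  fit$wald
}

#' Bonferroni-corrected pairwise comparisons of task-by-visit cell means
#'
#' Wald z-tests on all pairwise differences of the estimated task-by-visit
#' cell means (the default family: all pairs of the task x visit grid, 28
#' for 2 tasks x 4 visits), with the Bonferroni multiplier equal to the
#' family size. Cells absent from the data are flagged non-estimable
#' (their model-grid estimates are extrapolations), never silently dropped.
#'
#' @param fit A `limb_gee` object.
#' @param family `"all"` (every cell pair), `"task_within_visit"` (task
#'   contrasts at each visit) or `"visit_within_task"`.
#' @return Tibble: `cell_a, cell_b, estimate, std.error, z, p.value,
#'   adj.p.value, estimable`.
#' @export
bonferroni_pairwise <- function(fit, family = c("all", "task_within_visit",
                                                "visit_within_task")) {
  stopifnot(inherits(fit, "limb_gee"))
  family <- match.arg(family)
  cells <- fit$cells
  lab <- paste(cells$task, cells$visit, sep = ":")
  pairs <- utils::combn(nrow(cells), 2)
  keep <- switch(family,
    all = rep(TRUE, ncol(pairs)),
    task_within_visit = cells$visit[pairs[1, ]] == cells$visit[pairs[2, ]],
    visit_within_task = cells$task[pairs[1, ]] == cells$task[pairs[2, ]])
  pairs <- pairs[, keep, drop = FALSE]
  m_family <- ncol(pairs)
  purrr::map_dfr(seq_len(m_family), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    est <- cells$estimate[i] - cells$estimate[j]
    se <- sqrt(fit$cell_cov[i, i] + fit$cell_cov[j, j] - 2 * fit$cell_cov[i, j])
    z <- est / se
    praw <- if (identical(fit$test, "f")) {
      2 * stats::pt(-abs(z), fit$denom_df)
    } else {
      2 * pnorm(-abs(z))
    }
    tibble::tibble(cell_a = lab[i], cell_b = lab[j], estimate = est,
                   std.error = se, z = z, p.value = praw,
                   adj.p.value = min(1, m_family * praw),
                   estimable = cells$observed[i] && cells$observed[j])
  })
}

#' @export
print.limb_gee <- function(x, ...) {
  cat(sprintf("Marginal model (GEE): %s ~ task * visit\n", x$response))
  cat(sprintf("  %d observations, %d subjects; %s working correlation",
              x$n_obs, x$n_clusters, x$corstr))
  if (x$corstr != "independence") cat(sprintf(" (alpha = %.3f)", x$alpha))
  cat(sprintf("; %s sandwich\n", x$vcov_type))
  w <- x$wald
  for (k in seq_len(nrow(w)))
    cat(sprintf("  %-12s Wald chi2(%d) = %8.3f, p = %.4g\n",
                w$term[k], w$df[k], w$chisq[k], w$p.value[k]))
  invisible(x)
}

#' Tidy a fitted marginal model
#'
#' @param x A `limb_gee` object.
#' @param ... Unused.
#' @return Tibble of coefficients with robust standard errors:
#'   `term, estimate, std.error, statistic, p.value`.
#' @export
tidy.limb_gee <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  pv <- if (identical(x$test, "f")) 2 * stats::pt(-abs(z), x$denom_df)
        else 2 * pnorm(-abs(z))
  tibble::tibble(term = names(x$coefficients), estimate = x$coefficients,
                 std.error = se, statistic = z, p.value = pv)
}

#' One-row summary of a fitted marginal model
#'
#' @param x A `limb_gee` object.
#' @param ... Unused.
#' @return Tibble: `n_obs, n_clusters, alpha, scale, corstr, iterations`.
#' @export
glance.limb_gee <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_clusters = x$n_clusters, alpha = x$alpha,
                 scale = x$scale, corstr = x$corstr,
                 iterations = x$iterations)
}
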