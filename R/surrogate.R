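#' Shuffle each channel of a limb series
#'
#' Independently permutes the values of every channel uniformly at random,
#' destroying temporal structure while exactly preserving each channel's
#' value distribution. The canonical null for the line-based recurrence
#' measures: a shuffled series should show far shorter and fewer diagonal
#' lines than the observed one. Deterministic under `seed`.
#'
#' @param ms Limb series from [preprocess_session()] (or any data frame of
#'   channels; a `t` column is left in place).
#' @param seed Integer seed.
#' @return The series with every channel permuted; attributes preserved.
#' @export
shuffle_channels <- function(ms, seed = 1) {
  chans <- setdiff(names(ms), "t")
  with_seed(seed, {
    for (ch in chans) {
      v <- ms[[ch]]
      if (length(v) > 1) ms[[ch]] <- v[sample.int(length(v))]
    }
  })
  ms
}

#' Paired t-test of observed vs. surrogate measure values
#'
#' Two-sided paired t-test on matched per-session values of a recurrence
#' measure (observed minus shuffled). Degenerate inputs are handled
#' explicitly: all-zero differences give `t = 0, p = 1`; zero-variance
#' differences with non-zero mean give an infinite `t` and the smallest
#' representable p-value.
#'
#' @param observed,shuffled Equal-length paired numeric vectors (n >= 2).
#' @return One-row tibble: `t`, `df` (= n - 1), `p`, `n`.
#' @export
surrogate_test <- function(observed, shuffled) {
  if (length(observed) != length(shuffled))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(observed)
  if (n < 2) stop("need at least 2 paired sessions", call. = FALSE)
  d <- observed - shuffled
  if (all(d == 0)) {
    return(tibble::tibble(t = 0, df = n - 1L, p = 1, n = n))
  }
  # (numerically) constant non-zero differences: t diverges
  if (sd(d) <= .Machine$double.eps^0.5 * abs(mean(d))) {
    return(tibble::tibble(t = sign(mean(d)) * Inf, df = n - 1L,
                          p = .Machine$double.xmin, n = n))
  }
  tt <- t.test(observed, shuffled, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, n = n)
}

#' Surrogate control analysis of a measure table
#'
#' Pairs each session's observed recurrence measures with its shuffled
#' counterpart and runs [surrogate_test()] per visit (tasks pooled within a
#' visit) and per measure, mirroring the standard control-analysis report.
#'
#' @param observed,shuffled Measure tables (columns
#'   `subject, visit, task, ent, rr, ml`) for the observed and shuffled
#'   sessions; rows are matched on `(subject, visit, task)`.
#' @param measures Which measures to test.
#' @return Tibble: `visit, measure, t, df, p, n`.
#' @export
surrogate_analysis <- function(observed, shuffled,
                               measures = c("ent", "rr", "ml")) {
  key <- c("subject", "visit", "task")
  paired <- dplyr::inner_join(observed, shuffled, by = key,
                              suffix = c("_obs", "_shuf"))
  if (nrow(paired) == 0) stop("no matched sessions", call. = FALSE)
  grid <- tidyr::expand_grid(visit = intersect(VISITS, unique(paired$visit)),
                             measure = measures)
  purrr::pmap_dfr(grid, function(visit, measure) {
    sub <- paired[paired$visit == visit, ]
    res <- surrogate_test(sub[[paste0(measure, "_obs")]],
                          sub[[paste0(measure, "_shuf")]])
    dplyr::bind_cols(tibble::tibble(visit = visit, measure = measure), res)
  })
}
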