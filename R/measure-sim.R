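#' Default task-by-visit cell parameters for the measure simulator
#'
#' Mean and standard deviation of each recurrence measure in every
#' task-by-visit cell, used as the operating point of
#' [simulate_measure_table()]. The defaults describe a four-visit infant
#' cohort analysed at the 5% calibrated recurrence rate: entropy near
#' 5.1–5.7 nats, recurrence rate pinned near 5% at the calibration visit
#' and drifting apart between tasks afterwards, mean line around 15–24
#' samples — with the rhythmic (rattle) task pulling away from free play at
#' the third and fourth visits only, i.e. a task-by-age interaction with no
#' task difference at the first two visits.
#'
#' @param null If `TRUE`, every cell of a measure shares the measure's
#'   grand mean and pooled standard deviation — the no-effect null used for
#'   type-I-error calibration.
#' @return Tibble: `measure, task, visit, mean, sd`.
#' @export
measure_cell_defaults <- function(null = FALSE) {
  out <- tibble::tribble(
    ~measure, ~task,     ~visit, ~mean,  ~sd,
    "ent",    "rattle",   "T1",   5.51,  0.30,
    "ent",    "rattle",   "T2",   5.62,  0.44,
    "ent",    "rattle",   "T3",   5.72,  0.45,
    "ent",    "rattle",   "T4",   5.73,  0.37,
    "ent",    "freeplay", "T1",   5.46,  0.20,
    "ent",    "freeplay", "T2",   5.48,  0.42,
    "ent",    "freeplay", "T3",   5.10,  0.59,
    "ent",    "freeplay", "T4",   5.08,  0.42,
    "rr",     "rattle",   "T1",   5.03,  0.05,
    "rr",     "rattle",   "T2",   7.28,  5.13,
    "rr",     "rattle",   "T3",   9.17,  7.19,
    "rr",     "rattle",   "T4",   7.78,  5.01,
    "rr",     "freeplay", "T1",   5.05,  0.04,
    "rr",     "freeplay", "T2",   5.47,  3.84,
    "rr",     "freeplay", "T3",   4.51,  4.79,
    "rr",     "freeplay", "T4",   2.99,  3.52,
    "ml",     "rattle",   "T1",  19.48,  6.61,
    "ml",     "rattle",   "T2",  23.06,  8.59,
    "ml",     "rattle",   "T3",  23.55,  9.02,
    "ml",     "rattle",   "T4",  23.79,  5.78,
    "ml",     "freeplay", "T1",  18.96,  2.75,
    "ml",     "freeplay", "T2",  21.04,  7.36,
    "ml",     "freeplay", "T3",  16.15,  6.28,
    "ml",     "freeplay", "T4",  15.39,  4.53)
  if (null) {
    out <- out %>%
      dplyr::group_by(.data$measure) %>%
      dplyr::mutate(mean = mean(.data$mean),
                    sd = sqrt(mean(.data$sd^2))) %>%
      dplyr::ungroup()
  }
  out
}

#' Simulate a longitudinal measure table directly
#'
#' Draws a long measure table (`subject, visit, task, ent, rr, ml`) from a
#' Gaussian cell-mean model with a shared per-subject random intercept:
#' within each measure, `y = mu(task, visit) + sqrt(icc) * sd(cell) * b_s +
#' sqrt(1 - icc) * sd(cell) * e`, with `b_s ~ N(0,1)` common to all of a
#' subject's rows. This is the measure-level counterpart of the
#' signal-level simulator ([generate_cohort()] + the recurrence pipeline):
#' it reproduces the same longitudinal design — nested participation,
#' task-by-visit cell structure, within-subject dependence — at negligible
#' cost, which is what replicate-heavy power and type-I studies of the
#' repeated-measures stage need.
#'
#' @param n_per_visit Subjects contributing at each visit (nested
#'   participation as in [cohort_design()]).
#' @param cell_params Cell means/sds from [measure_cell_defaults()].
#' @param icc Fraction of each cell's variance carried by the subject
#'   random intercept (default 0.5).
#' @param seed Integer seed.
#' @return Tibble: `subject, visit, task, ent, rr, ml`.
#' @export
simulate_measure_table <- function(n_per_visit = c(T1 = 19, T2 = 21,
                                                   T3 = 26, T4 = 17),
                                   cell_params = measure_cell_defaults(),
                                   icc = 0.5, seed = 1) {
  stopifnot(length(n_per_visit) == 4, icc >= 0, icc <= 1)
  n_max <- max(n_per_visit)
  subjects <- sprintf("s%02d", seq_len(n_max))
  rows <- purrr::map_dfr(seq_along(VISITS), function(v) {
    n_v <- n_per_visit[[v]]
    if (n_v == 0) return(NULL)
    tidyr::expand_grid(subject = subjects[seq_len(n_v)], visit = VISITS[v],
                       task = TASKS)
  })
  measures <- unique(cell_params$measure)
  with_seed(seed, {
    b <- stats::setNames(
      lapply(measures, function(m) stats::setNames(rnorm(n_max), subjects)),
      measures)
    for (m in measures) {
      cp <- cell_params[cell_params$measure == m, ]
      idx <- match(paste(rows$task, rows$visit),
                   paste(cp$task, cp$visit))
      mu <- cp$mean[idx]
      s <- cp$sd[idx]
      rows[[m]] <- mu + sqrt(icc) * s * b[[m]][rows$subject] +
        sqrt(1 - icc) * s * rnorm(nrow(rows))
    }
  })
  rows
}
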