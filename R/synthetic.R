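#' Regime parameters for a simulated movement session
#'
#' Bundles the knobs of the two movement regimes the simulator can produce:
#' `"rhythmic"` — all four limbs oscillate at a shared frequency with a
#' tunable degree of inter-limb phase coupling and phase regularity, the
#' caricature of rattle-shaking; `"unstructured"` — intermittent random
#' movement bursts on a quiet baseline with no stable dominant frequency,
#' the caricature of free play.
#'
#' @param regime `"rhythmic"` or `"unstructured"`.
#' @param duration_s Session duration in seconds.
#' @param osc_freq_hz Oscillation frequency of the rhythmic regime (Hz);
#'   must stay below the Nyquist frequency of the sampling rate.
#' @param coupling Shared-phase weight across limbs in `[0, 1]`; 1 means all
#'   limbs follow one common phase, 0 means fully independent phases.
#' @param arm_leg_ratio Amplitude ratio of arms to legs in the rhythmic
#'   regime (arm-led rattle-shaking; default 2).
#' @param burst_rate_hz Poisson rate of movement bursts (unstructured only).
#' @param burst_len_s Mean burst duration in seconds (unstructured only).
#' @param noise_sd Additive per-axis sensor noise, m/s^2.
#' @param regularity Phase regularity in `[0, 1]`: higher values shrink the
#'   random-walk phase jitter of the rhythmic regime, giving more periodic
#'   movement. The longitudinal task-by-age interaction is encoded by
#'   raising this value at later visits for the rhythmic task only.
#' @return A list of class `"regime_params"`.
#' @export
#' @examples
#' regime_params("rhythmic", duration_s = 10, osc_freq_hz = 2.5)
regime_params <- function(regime = c("rhythmic", "unstructured"),
                          duration_s = 50,
                          osc_freq_hz = 2.5,
                          coupling = 0.8,
                          arm_leg_ratio = 2,
                          burst_rate_hz = 0.4,
                          burst_len_s = 1,
                          noise_sd = 0.1,
                          regularity = 0.55) {
  regime <- match.arg(regime)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive", call. = FALSE)
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]", call. = FALSE)
  if (regularity < 0 || regularity > 1)
    stop("regularity must lie in [0, 1]", call. = FALSE)
  if (osc_freq_hz <= 0) stop("osc_freq_hz must be positive", call. = FALSE)
  structure(list(regime = regime, duration_s = duration_s,
                 osc_freq_hz = osc_freq_hz, coupling = coupling,
                 arm_leg_ratio = arm_leg_ratio, burst_rate_hz = burst_rate_hz,
                 burst_len_s = burst_len_s, noise_sd = noise_sd,
                 regularity = regularity),
            class = "regime_params")
}

# First-order autoregressive smoother used to produce slowly wandering
# processes (sensor orientation wobble, burst envelopes). Unit variance.
ar1_noise <- function(n, phi = 0.98) {
  as.numeric(stats::filter(rnorm(n), phi, method = "recursive")) *
    sqrt(1 - phi^2)
}

# Simulate the 3-axis trace of one limb given its magnitude envelope.
# The acceleration vector follows a slowly wobbling unit direction scaled by
# the envelope, plus white sensor noise per axis, so the per-sample magnitude
# tracks the envelope closely.
limb_axes <- function(envelope, noise_sd) {
  n <- length(envelope)
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  wob <- vapply(1:3, function(i) 0.15 * ar1_noise(n), numeric(n))
  d <- sweep(wob, 2, u, `+`)
  d <- d / sqrt(rowSums(d^2))
  d * envelope + matrix(rnorm(3L * n, sd = noise_sd), ncol = 3)
}

rhythmic_envelopes <- function(n, rate_hz, p) {
  t <- (seq_len(n) - 1) / rate_hz
  jitter_sd <- 0.15 * (1 - p$regularity)
  shared <- cumsum(rnorm(n, sd = jitter_sd))
  lapply(LIMBS, function(limb) {
    own <- cumsum(rnorm(n, sd = jitter_sd))
    phase <- 2 * pi * p$osc_freq_hz * t +
      p$coupling * shared + (1 - p$coupling) * own + runif(1, 0, 2 * pi)
    amp <- if (grepl("arm", limb)) 3 else 3 / p$arm_leg_ratio
    amp * (1 + 0.9 * sin(phase))
  })
}

unstructured_envelopes <- function(n, rate_hz, p) {
  lapply(LIMBS, function(limb) {
    env <- rep(0.3, n)
    n_bursts <- rpois(1, p$burst_rate_hz * n / rate_hz)
    if (n_bursts > 0) {
      for (b in seq_len(n_bursts)) {
        len <- max(round(rate_hz * min(max(rexp(1, 1 / p$burst_len_s), 0.2), 4)), 3L)
        start <- sample.int(max(n - len, 1L), 1L)
        idx <- start:min(start + len - 1L, n)
        shape <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
        env[idx] <- env[idx] + 3 * runif(1, 0.5, 1.5) * shape
      }
    }
    env * (1 + 0.3 * abs(ar1_noise(n, 0.9)))
  })
}

#' Simulate one four-limb accelerometer session
#'
#' Generates 3-axis acceleration for the four limb sensors at the given
#' sampling rate under either movement regime. Output is a tidy tibble with
#' one row per (limb, sample); magnitudes of the rhythmic regime carry a
#' dominant spectral peak at `osc_freq_hz` shared across limbs, while the
#' unstructured regime has no stable dominant peak. Identical
#' `(params, seed)` give bit-identical output.
#'
#' @param subject Subject identifier.
#' @param visit Visit label, one of `"T1" .. "T4"`.
#' @param task Task label, `"rattle"` or `"freeplay"` (metadata only; the
#'   dynamics come from `params$regime`).
#' @param params A [regime_params()] object.
#' @param seed Integer seed; all randomness derives from it.
#' @param rate_hz Sampling rate (default 60 Hz).
#' @return Tibble with columns `subject, visit, task, limb, t, ax, ay, az`;
#'   sampling rate recorded in attribute `"rate_hz"`.
#' @export
#' @examples
#' s <- generate_session("s01", "T1", "rattle",
#'                       regime_params("rhythmic", duration_s = 5), seed = 1)
#' dplyr::count(s, limb)
generate_session <- function(subject, visit, task, params, seed, rate_hz = 60) {
  stopifnot(inherits(params, "regime_params"))
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  if (params$regime == "rhythmic" && params$osc_freq_hz >= rate_hz / 2)
    stop("osc_freq_hz must be below the Nyquist frequency", call. = FALSE)
  n <- round(params$duration_s * rate_hz)
  if (n < 2) stop("duration too short for the sampling rate", call. = FALSE)
  with_seed(seed, {
    envs <- if (params$regime == "rhythmic") {
      rhythmic_envelopes(n, rate_hz, params)
    } else {
      unstructured_envelopes(n, rate_hz, params)
    }
    out <- purrr::map2_dfr(LIMBS, envs, function(limb, env) {
      xyz <- limb_axes(env, params$noise_sd)
      tibble::tibble(subject = subject, visit = visit, task = task,
                     limb = limb, t = (seq_len(n) - 1) / rate_hz,
                     ax = xyz[, 1], ay = xyz[, 2], az = xyz[, 3])
    })
    attr(out, "rate_hz") <- rate_hz
    out
  })
}

#' Inject bursty missingness into a session
#'
#' Marks contiguous runs of samples missing (all three axes set to `NA`)
#' within each limb, emulating sensor dropouts. Gap lengths are geometric
#' with the given mean; gaps are placed without overlap in the interior of
#' the series, never touching the first or last sample, until the per-limb
#' missing fraction reaches `missing_rate` (within one percentage point).
#' Non-missing samples are untouched.
#'
#' @param session Tidy session tibble from [generate_session()].
#' @param missing_rate Target fraction of missing samples in `[0, 1)`
#'   (default 0.101, a typical wearable-sensor dropout rate).
#' @param mean_gap Mean gap length in samples (default 5).
#' @param seed Integer seed.
#' @return The session with `NA` runs in `ax, ay, az`.
#' @export
inject_missing <- function(session, missing_rate = 0.101, mean_gap = 5, seed = 1) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (mean_gap < 1) stop("mean_gap must be >= 1", call. = FALSE)
  if (missing_rate == 0) return(session)
  with_seed(seed, {
    key <- paste(session$subject, session$visit, session$task, session$limb,
                 sep = "\r")
    for (k in unique(key)) {  # order of first appearance: deterministic
      rows <- which(key == k)
      n <- length(rows)
      target <- round(missing_rate * n)
      miss <- rep(FALSE, n)
      attempts <- 0L
      while (sum(miss) < target && attempts < 200L * n) {
        attempts <- attempts + 1L
        len <- min(1L + rgeom(1, 1 / mean_gap), target - sum(miss))
        if (len < 1L || n - len < 2L) next
        start <- sample(2:(n - len), 1L)
        idx <- start:(start + len - 1L)
        if (any(miss[idx])) next
        miss[idx] <- TRUE
      }
      gone <- rows[miss]
      session$ax[gone] <- NA_real_
      session$ay[gone] <- NA_real_
      session$az[gone] <- NA_real_
    }
    session
  })
}

#' Longitudinal cohort design
#'
#' Describes a four-visit, two-task longitudinal accelerometry study: how
#' many subjects contribute at each visit, how long each task's session is,
#' how much missingness to inject, and — crucially — the built-in
#' task-by-visit interaction: `effect` gives the per-visit increment of the
#' rhythmic regime's `regularity`, applied to the rattle task only, so task
#' differences in the recurrence measures emerge at the visits where the
#' increment is non-zero. The default raises regularity at T3/T4 only.
#'
#' Participation is nested and deterministic: subjects are labelled
#' `s01, s02, ...` up to the largest per-visit count, and visit `v` is
#' attended by the first `n_per_visit[v]` subjects, giving the unbalanced
#' overlap structure typical of longitudinal infant cohorts.
#'
#' @param n_per_visit Named or positional counts for visits T1..T4
#'   (default `c(19, 21, 26, 17)`, a realistic attrition pattern).
#' @param tasks Tasks run at every visit.
#' @param effect Per-visit regularity increments for the rhythmic task.
#' @param missing_rate,mean_gap Missingness injection parameters.
#' @param rattle_s,freeplay_s Session durations in seconds. Defaults are
#'   desk-scale (50 s / 100 s); field sessions would be roughly 300/600 s.
#' @param rate_hz Sampling rate.
#' @param base_regularity Rhythmic-regime regularity at visits with zero
#'   increment.
#' @param noise_sd Sensor noise passed to both regimes.
#' @param seed Master seed; per-session seeds are derived from it.
#' @return A list of class `"cohort_design"`.
#' @export
cohort_design <- function(n_per_visit = c(T1 = 19, T2 = 21, T3 = 26, T4 = 17),
                          tasks = TASKS,
                          effect = c(T1 = 0, T2 = 0, T3 = 0.25, T4 = 0.30),
                          missing_rate = 0.101, mean_gap = 5,
                          rattle_s = 50, freeplay_s = 100,
                          rate_hz = 60, base_regularity = 0.55,
                          noise_sd = 0.1, seed = 1) {
  if (length(n_per_visit) != 4) stop("n_per_visit needs 4 counts", call. = FALSE)
  if (any(n_per_visit < 0)) stop("visit counts must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  n_per_visit <- stats::setNames(as.integer(n_per_visit), VISITS)
  effect <- stats::setNames(as.numeric(effect), VISITS)
  structure(list(n_per_visit = n_per_visit, tasks = tasks, effect = effect,
                 missing_rate = missing_rate, mean_gap = mean_gap,
                 rattle_s = rattle_s, freeplay_s = freeplay_s,
                 rate_hz = rate_hz, base_regularity = base_regularity,
                 noise_sd = noise_sd, seed = seed),
            class = "cohort_design")
}

#' Generate a longitudinal cohort of sessions
#'
#' Produces one session per (subject, visit, task) cell of the design, with
#' the rattle task driven by the rhythmic regime (regularity rising across
#' visits per `design$effect`) and free play by the unstructured regime
#' (visit-invariant), then injects missingness. Fully deterministic under
#' the design's seed.
#'
#' @param design A [cohort_design()].
#' @return One long tidy tibble of all sessions (schema of
#'   [generate_session()]); the design is attached as attribute `"design"`.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  if (sum(design$n_per_visit) == 0) stop("empty design", call. = FALSE)
  n_max <- max(design$n_per_visit)
  subjects <- sprintf("s%02d", seq_len(n_max))
  cells <- purrr::map_dfr(VISITS, function(v) {
    n_v <- design$n_per_visit[[v]]
    if (n_v == 0) return(NULL)
    tidyr::expand_grid(subject = subjects[seq_len(n_v)], visit = v,
                       task = design$tasks)
  })
  seeds <- with_seed(design$seed, {
    matrix(sample.int(2^31 - 2, 2L * nrow(cells)), ncol = 2)
  })
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    if (cell$task == "rattle") {
      reg <- min(design$base_regularity + design$effect[[cell$visit]], 0.98)
      p <- regime_params("rhythmic", duration_s = design$rattle_s,
                         regularity = reg, noise_sd = design$noise_sd)
    } else {
      p <- regime_params("unstructured", duration_s = design$freeplay_s,
                         regularity = design$base_regularity,
                         noise_sd = design$noise_sd)
    }
    s <- generate_session(cell$subject, cell$visit, cell$task, p,
                          seed = seeds[i, 1], rate_hz = design$rate_hz)
    inject_missing(s, design$missing_rate, design$mean_gap, seed = seeds[i, 2])
  })
  attr(out, "rate_hz") <- design$rate_hz
  attr(out, "design") <- design
  out
}
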