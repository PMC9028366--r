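#' Embedding delay by average mutual information
#'
#' Computes, for each channel, the mutual information between `x(t)` and
#' `x(t + lag)` from a 2-D histogram with `n_bins` equal-width bins per
#' margin, for lags `0 .. max_lag`; averages the AMI curves across channels;
#' and returns the first local minimum of the averaged curve — the first lag
#' `k >= 1` with `I(k-1) > I(k) <= I(k+1)`. If the curve has no local
#' minimum over the range, the argmin is returned and the result carries
#' attribute `no_local_minimum = TRUE` (with a warning).
#'
#' @param ms Limb series, data frame of channels, or numeric matrix/vector.
#' @param max_lag Largest lag to scan (must be < N/2).
#' @param n_bins Histogram bins per margin (default 10).
#' @return Integer delay in samples; attribute `ami` holds the averaged
#'   curve (lags `0..max_lag`).
#' @export
ami_delay <- function(ms, max_lag = 60, n_bins = 10) {
  x <- as_channel_matrix(ms)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (max_lag >= n / 2) stop("series too short for max_lag", call. = FALSE)
  if (max_lag < 1) stop("max_lag must be >= 1", call. = FALSE)
  curves <- apply(x, 2, function(v) {
    vapply(0:max_lag, function(lag) {
      mutual_information(v[1:(n - lag)], v[(1 + lag):n], n_bins)
    }, numeric(1))
  })
  avg <- rowMeans(curves)
  # first local minimum: I(k-1) > I(k) <= I(k+1)
  tau <- NA_integer_
  if (max_lag >= 2) {
    for (k in 1:(max_lag - 1)) {
      if (avg[k] > avg[k + 1] && avg[k + 1] <= avg[k + 2]) {
        tau <- k
        break
      }
    }
  }
  no_min <- is.na(tau)
  if (no_min) {
    tau <- which.min(avg[-1])  # argmin over lags 1..max_lag
    warning("AMI curve has no local minimum over the scanned range; ",
            "returning its argmin", call. = FALSE)
  }
  structure(as.integer(tau), ami = avg, no_local_minimum = no_min)
}

# Plug-in mutual information (nats) from an equal-width 2-D histogram.
mutual_information <- function(a, b, n_bins) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ia <- pmin(findInterval(a, seq(ra[1], ra[2], length.out = n_bins + 1),
                          rightmost.closed = TRUE), n_bins)
  ib <- pmin(findInterval(b, seq(rb[1], rb[2], length.out = n_bins + 1),
                          rightmost.closed = TRUE), n_bins)
  joint <- tabulate(ia + n_bins * (ib - 1L), nbins = n_bins * n_bins)
  p <- joint / length(a)
  pm <- matrix(p, n_bins, n_bins)
  pa <- rowSums(pm); pb <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / outer(pa, pb)[nz]))
}

#' Embedding dimension by false nearest neighbours
#'
#' Embeds all channels jointly at dimensions `1 .. max_dim` with delay
#' `tau`, finds each state's nearest neighbour (excluding states within
#' `theiler` samples in time), and marks the neighbour false when the
#' distance added by the next dimension's coordinates exceeds `rtol` times
#' the current distance, or when the expanded distance exceeds `atol` times
#' the attractor size (the classical two-criterion rule). Returns the
#' smallest dimension whose false-neighbour fraction drops below
#' `threshold`; if none does, `max_dim` is returned with a warning and
#' attribute `no_plateau = TRUE`.
#'
#' @param ms Limb series, data frame, or numeric matrix/vector.
#' @param tau Embedding delay in samples.
#' @param max_dim Largest dimension to test.
#' @param rtol,atol False-neighbour criteria (defaults 10 and 2).
#' @param threshold False-neighbour fraction cutoff (default 0.10).
#' @param theiler Temporal exclusion half-width for the neighbour search.
#' @return Integer dimension; attribute `fnn` holds the per-dimension
#'   false-neighbour fractions.
#' @export
fnn_dimension <- function(ms, tau, max_dim = 12, rtol = 10, atol = 2,
                          threshold = 0.10, theiler = 1) {
  x <- as_channel_matrix(ms)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (max_dim < 1) stop("max_dim must be >= 1", call. = FALSE)
  if (nrow(x) <= (max_dim) * tau + 1) stop("series too short", call. = FALSE)
  frac <- fnn_fractions(x, as.integer(tau), as.integer(max_dim),
                        rtol, atol, as.integer(theiler))
  ok <- which(!is.na(frac) & frac < threshold)
  if (length(ok)) {
    structure(as.integer(ok[1]), fnn = frac, no_plateau = FALSE)
  } else {
    warning("false-neighbour fraction never fell below the cutoff; ",
            "returning max_dim", call. = FALSE)
    structure(as.integer(max_dim), fnn = frac, no_plateau = TRUE)
  }
}

#' Time-delay embedding of a multichannel series
#'
#' Builds the joint state matrix: row `t` concatenates, for every channel
#' `d` and lag `j = 0 .. m-1`, the value `x_d(t + j * tau)`, giving
#' `N - (m-1) * tau` state vectors of `D * m` coordinates.
#'
#' @param ms Limb series, data frame, or numeric matrix.
#' @param tau Delay in samples (>= 1).
#' @param m Embedding dimension per channel (>= 1).
#' @return Numeric state matrix with attributes `tau`, `m`, `channels`.
#' @export
embed_multidim <- function(ms, tau, m) {
  x <- as_channel_matrix(ms)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  tau <- as.integer(tau); m <- as.integer(m)
  if (tau < 1 || m < 1) stop("tau and m must be >= 1", call. = FALSE)
  n <- nrow(x); d <- ncol(x)
  np <- n - (m - 1L) * tau
  if (np < 2) stop("series too short for this (m, tau)", call. = FALSE)
  out <- matrix(0, np, d * m)
  for (ch in seq_len(d))
    for (j in seq_len(m) - 1L)
      out[, (ch - 1L) * m + j + 1L] <- x[(1L + j * tau):(np + j * tau), ch]
  structure(out, tau = tau, m = m, channels = colnames(x))
}

#' Calibrate the recurrence radius to a target recurrence rate
#'
#' Bisects the radius between 0 and the maximum pairwise state distance
#' until the recurrence rate (Theiler-excluded density of recurrent cells,
#' the same convention as [rqa_measures()]) is within `tol` percentage
#' points of `target_rr`. RR is non-decreasing in the radius, so bisection
#' is valid. Fixing RR across subjects makes the line-based measures
#' comparable; 5% is the conventional sparse operating point.
#'
#' @param states State matrix from [embed_multidim()].
#' @param target_rr Target recurrence rate, percent (default 5).
#' @param tol Tolerance in percentage points (default 0.1).
#' @param theiler Theiler half-width (default 1: main diagonal excluded).
#' @param max_iter Bisection iteration cap (default 60).
#' @return Radius (numeric scalar) with attributes `achieved_rr` and
#'   `iterations`.
#' @export
calibrate_radius <- function(states, target_rr = 5, tol = 0.1, theiler = 1,
                             max_iter = 60) {
  if (target_rr <= 0 || target_rr >= 100)
    stop("target_rr must lie in (0, 100)", call. = FALSE)
  hi <- max_pair_dist(states)
  if (hi == 0)
    stop("degenerate state matrix: all states identical (RR = 100% for any ",
         "positive radius); radius calibration failed", call. = FALSE)
  rr_at <- function(eps) {
    s <- rqa_stream(states, eps, as.integer(theiler), 2L, FALSE)
    100 * s$recurrent / s$cells
  }
  lo <- 0
  eps <- hi
  rr <- rr_at(eps)
  it <- 0L
  while (abs(rr - target_rr) > tol && it < max_iter) {
    it <- it + 1L
    eps <- (lo + hi) / 2
    rr <- rr_at(eps)
    if (rr < target_rr) lo <- eps else hi <- eps
  }
  if (abs(rr - target_rr) > tol)
    warning(sprintf("radius calibration stopped at RR = %.3f%% (target %g%%)",
                    rr, target_rr), call. = FALSE)
  structure(eps, achieved_rr = rr, iterations = it)
}

#' Estimate and fix embedding parameters per subject
#'
#' For each subject (and task, by default), estimates the embedding delay,
#' dimension and radius on the earliest available visit — the anchor — and
#' fixes them for all later visits, so changes in the recurrence measures
#' over age reflect changing dynamics rather than changing parameters.
#' Supply `tau` and/or `m` to skip estimation and use a preset (e.g. the
#' delay-1, dimension-14 operating point typical for such biological
#' signals); the radius is always calibrated on the anchor visit.
#'
#' @param sessions Long tidy tibble of raw sessions (a cohort).
#' @param target_rr Target recurrence rate, percent.
#' @param tau,m Optional presets; `NULL` means estimate via [ami_delay()] /
#'   [fnn_dimension()] on the anchor visit.
#' @param per_task Calibrate each task separately (default) or pool tasks by
#'   anchoring on the subject's earliest session regardless of task.
#' @param max_lag,n_bins Passed to [ami_delay()] when estimating.
#' @param max_dim Passed to [fnn_dimension()] when estimating.
#' @param theiler,tol Passed to [calibrate_radius()].
#' @return Tibble: `subject, task, anchor_visit, tau, m, epsilon, target_rr`
#'   (one row per subject, or per subject x task).
#' @export
fix_params_per_subject <- function(sessions, target_rr = 5, tau = NULL,
                                   m = NULL, per_task = TRUE, max_lag = 30,
                                   n_bins = 10, max_dim = 12, theiler = 1,
                                   tol = 0.1) {
  groups <- if (per_task) c("subject", "task") else "subject"
  keys <- dplyr::distinct(sessions, dplyr::across(dplyr::all_of(groups)))
  if (nrow(keys) == 0) stop("no sessions", call. = FALSE)
  purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    key <- keys[i, ]
    sub <- dplyr::semi_join(sessions, key, by = groups)
    anchor <- VISITS[min(match(unique(sub$visit), VISITS))]
    one <- sub[sub$visit == anchor, ]
    if (!per_task) one <- one[one$task == one$task[1], ]
    ms <- preprocess_session(one)
    tau_i <- if (is.null(tau)) as.integer(ami_delay(ms, max_lag, n_bins)) else as.integer(tau)
    m_i <- if (is.null(m)) as.integer(fnn_dimension(ms, tau_i, max_dim)) else as.integer(m)
    st <- embed_multidim(ms, tau_i, m_i)
    eps <- calibrate_radius(st, target_rr, tol = tol, theiler = theiler)
    tibble::tibble(subject = key$subject,
                   task = if (per_task) key$task else NA_character_,
                   anchor_visit = anchor, tau = tau_i, m = m_i,
                   epsilon = as.numeric(eps), target_rr = target_rr)
  })
}
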