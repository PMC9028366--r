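#' Interpolate missing samples with a cubic spline
#'
#' Interior missing samples are replaced by the cubic-spline value fitted
#' through the non-missing samples at their integer sample indices; leading
#' and trailing missing samples are filled with the nearest valid value
#' (spline extrapolation beyond the observed range can explode, so it is
#' never used at the edges). Non-missing samples pass through unchanged.
#'
#' @param x Numeric vector; `NA` marks missing samples.
#' @return Numeric vector without `NA`.
#' @export
#' @examples
#' fill_missing(c(0, 1, NA, 3, 4))  # spline through a line is the line
fill_missing <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 4) stop("need at least 4 non-missing samples", call. = FALSE)
  if (all(ok)) return(x)
  idx <- seq_along(x)
  first_ok <- which(ok)[1]
  last_ok <- which(ok)[sum(ok)]
  interior <- which(!ok & idx > first_ok & idx < last_ok)
  if (length(interior)) {
    x[interior] <- spline(idx[ok], x[ok], xout = interior, method = "fmm")$y
  }
  if (first_ok > 1) x[seq_len(first_ok - 1)] <- x[first_ok]
  if (last_ok < length(x)) x[(last_ok + 1):length(x)] <- x[last_ok]
  x
}

#' Collapse 3-axis acceleration to its magnitude
#'
#' @param ax,ay,az Equal-length numeric vectors, m/s^2.
#' @return `sqrt(ax^2 + ay^2 + az^2)`, elementwise.
#' @export
accel_magnitude <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("axis vectors must have equal length", call. = FALSE)
  sqrt(ax^2 + ay^2 + az^2)
}

#' Third-order (3-point) median filter
#'
#' Replaces each interior sample with the median of itself and its two
#' neighbours, removing one-point outliers. Endpoints use the truncated
#' window: the median of the two available samples, i.e. their mean.
#' (Zero-padding the ends — as some filter implementations do — would
#' inject spurious zeros into acceleration magnitudes, so the truncated
#' window is used deliberately.)
#'
#' @param x Numeric vector.
#' @return Filtered vector, same length.
#' @export
#' @examples
#' median_smooth(c(5, 100, 5, 5))
median_smooth <- function(x) {
  n <- length(x)
  if (n <= 1) return(x)
  if (n == 2) return(rep(mean(x), 2))
  lo <- x[1:(n - 2)]; mid <- x[2:(n - 1)]; hi <- x[3:n]
  interior <- lo + mid + hi - pmax(lo, mid, hi) - pmin(lo, mid, hi)
  c(mean(x[1:2]), interior, mean(x[(n - 1):n]))
}

#' z-score a series (sample standard deviation)
#'
#' @param x Numeric vector with positive variance.
#' @return `(x - mean(x)) / sd(x)`; mean 0, sample sd 1.
#' @export
standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("constant series cannot be standardized (unusable channel)",
         call. = FALSE)
  (x - mean(x)) / s
}

#' Preprocess a raw session into standardized magnitude channels
#'
#' Applies, per limb and in this fixed order: cubic-spline interpolation of
#' missing samples (per axis — the sensor drops axes, and the magnitude of
#' interpolated axes differs from interpolating magnitudes), collapse to
#' acceleration magnitude, 3-point median smoothing, z-scoring. The raw
#' per-limb missing fraction is recorded before any filling.
#'
#' @param session Tidy session tibble (columns
#'   `subject, visit, task, limb, t, ax, ay, az`; `NA` = missing sample).
#' @return A "limb series": wide tibble with column `t` and one standardized
#'   magnitude column per limb, carrying attributes `meta` (subject, visit,
#'   task), `rate_hz` and `missing_fraction` (named per-limb vector).
#' @export
preprocess_session <- function(session) {
  need <- c("subject", "visit", "task", "limb", "t", "ax", "ay", "az")
  missing_cols <- setdiff(need, names(session))
  if (length(missing_cols))
    stop("session lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  meta <- dplyr::distinct(session, .data$subject, .data$visit, .data$task)
  if (nrow(meta) != 1)
    stop("preprocess_session expects a single (subject, visit, task) session",
         call. = FALSE)
  limbs <- intersect(LIMBS, unique(session$limb))
  if (length(limbs) != 4) stop("session must contain all four limbs", call. = FALSE)
  rate_hz <- attr(session, "rate_hz")
  if (is.null(rate_hz)) {
    t1 <- session$t[session$limb == limbs[1]]
    rate_hz <- 1 / median(diff(t1))
  }
  cols <- lapply(limbs, function(l) {
    df <- session[session$limb == l, ]
    df <- df[order(df$t), ]
    mag <- accel_magnitude(fill_missing(df$ax), fill_missing(df$ay),
                           fill_missing(df$az))
    standardize(median_smooth(mag))
  })
  ns <- lengths(cols)
  if (length(unique(ns)) != 1) stop("limbs have unequal lengths", call. = FALSE)
  miss <- vapply(limbs, function(l) {
    df <- session[session$limb == l, ]
    mean(is.na(df$ax) | is.na(df$ay) | is.na(df$az))
  }, numeric(1))
  out <- tibble::as_tibble(stats::setNames(cols, limbs))
  out <- dplyr::bind_cols(tibble::tibble(t = (seq_len(ns[1]) - 1) / rate_hz), out)
  attr(out, "meta") <- as.list(meta)
  attr(out, "rate_hz") <- rate_hz
  attr(out, "missing_fraction") <- miss
  class(out) <- c("limb_series", class(out))
  out
}

#' Channel matrix of a preprocessed limb series
#'
#' @param ms A limb series from [preprocess_session()], or any data frame of
#'   numeric channels (a `t` column, if present, is dropped).
#' @return Numeric matrix, samples x channels.
#' @export
as_channel_matrix <- function(ms) {
  if (is.matrix(ms)) return(ms)
  df <- as.data.frame(ms)
  df$t <- NULL
  as.matrix(df)
}

#' Per-channel raw missing fraction of a limb series
#' @param ms A limb series from [preprocess_session()].
#' @return Named numeric vector.
#' @export
missing_fraction <- function(ms) attr(ms, "missing_fraction")
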