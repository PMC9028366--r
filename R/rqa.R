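#' RQA configuration
#'
#' Conventions for the recurrence plot and its line-based measures:
#' `lmin` — minimum diagonal line length counted (default 2, the standard
#' convention); `theiler` — half-width of the main-diagonal exclusion band:
#' diagonals at offset `|i - j| < theiler` are dropped from both the
#' recurrence-rate numerator/denominator and the line counting, so the
#' default 1 excludes exactly the trivial self-recurrences of the main
#' diagonal and 0 excludes nothing; `log_base` — base of the entropy
#' logarithm (default `exp(1)`, nats).
#'
#' @param lmin Minimum diagonal line length (>= 2).
#' @param theiler Theiler half-width (>= 0; 0 would include the main
#'   diagonal).
#' @param log_base Entropy logarithm base.
#' @return List of class `"rqa_config"`.
#' @export
rqa_config <- function(lmin = 2, theiler = 1, log_base = exp(1)) {
  if (lmin < 2) stop("lmin must be >= 2", call. = FALSE)
  if (theiler < 0) stop("theiler must be >= 0", call. = FALSE)
  structure(list(lmin = as.integer(lmin), theiler = as.integer(theiler),
                 log_base = log_base),
            class = "rqa_config")
}

#' Thresholded recurrence plot (full matrix)
#'
#' Materializes the binary recurrence matrix: `R[i, j] = 1` iff the
#' Euclidean distance between states `i` and `j` is at most `epsilon`.
#' Intended for inspection, plotting and cross-checking at small N; the
#' measures themselves are normally computed by the streaming kernel of
#' [rqa_measures()], which never builds this matrix.
#'
#' @param states State matrix from [embed_multidim()].
#' @param epsilon Recurrence radius (> 0).
#' @param config An [rqa_config()].
#' @return Object of class `"limb_rp"`: list with the binary `matrix`,
#'   `epsilon` and `config`.
#' @export
recurrence_plot <- function(states, epsilon, config = rqa_config()) {
  if (!is.matrix(states)) states <- as_channel_matrix(states)
  if (nrow(states) < 1) stop("empty state matrix", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  structure(list(matrix = recurrence_matrix_full(states, epsilon),
                 epsilon = epsilon, config = config),
            class = "limb_rp")
}

#' @export
print.limb_rp <- function(x, ...) {
  n <- nrow(x$matrix)
  off <- abs(row(x$matrix) - col(x$matrix)) >= x$config$theiler
  cat(sprintf("Recurrence plot: %d x %d states, epsilon = %.4g, RR = %.2f%%\n",
              n, n, x$epsilon, 100 * mean(x$matrix[off])))
  invisible(x)
}

#' Diagonal line-length histogram of a recurrence plot
#'
#' Counts maximal runs of recurrent cells along every diagonal at offset
#' `|k| >= theiler` (both triangles), keeping runs of length at least
#' `lmin`. A run is maximal when bounded by non-recurrent cells or the plot
#' edge. This is the full-matrix route; [rqa_measures()] produces the same
#' histogram by a streaming pass.
#'
#' @param rp A `limb_rp` object or a binary 0/1 matrix.
#' @param config An [rqa_config()].
#' @return Tibble with columns `length` and `count`.
#' @export
diagonal_histogram <- function(rp, config = rqa_config()) {
  if (inherits(rp, "limb_rp")) {
    config <- rp$config
    rp <- rp$matrix
  }
  n <- nrow(rp)
  counts <- integer(0)
  lens <- integer(0)
  offsets <- seq(-(n - 1), n - 1)
  offsets <- offsets[abs(offsets) >= config$theiler]
  for (k in offsets) {
    i <- if (k >= 0) seq_len(n - k) else seq_len(n + k) - k
    j <- i + k
    d <- rp[cbind(i, j)]
    r <- rle(d)
    runs <- r$lengths[r$values == 1 & r$lengths >= config$lmin]
    lens <- c(lens, runs)
  }
  if (length(lens) == 0)
    return(tibble::tibble(length = integer(0), count = integer(0)))
  tab <- table(lens)
  tibble::tibble(length = as.integer(names(tab)), count = as.integer(tab))
}

# Measures from a line histogram (tibble length/count) plus the recurrence
# rate; empty histogram gives Ent = 0, ML = 0 by convention.
measures_from_histogram <- function(hist, rr, config) {
  total <- sum(hist$count)
  if (total == 0) {
    ent <- 0; ml <- 0
  } else {
    p <- hist$count / total
    ent <- -sum(p * log(p, base = config$log_base))
    ml <- sum(hist$length * hist$count) / total
  }
  tibble::tibble(rr = rr, ent = ent, ml = ml, n_lines = total)
}

#' MdRQA measures from embedded states (streaming)
#'
#' Computes the three recurrence measures without materializing the
#' recurrence matrix, by walking each diagonal of the implicit plot once
#' (O(N^2) time, O(N) memory):
#' \itemize{
#'   \item RR — recurrence rate: 100 x (recurrent cells with
#'     `|i-j| >= theiler`) / (cells with `|i-j| >= theiler`);
#'   \item Ent — Shannon entropy of the diagonal line-length distribution,
#'     `-sum p(l) log p(l)`;
#'   \item ML — mean diagonal line length, `sum l P(l) / sum P(l)`.
#' }
#'
#' @param states State matrix from [embed_multidim()].
#' @param epsilon Recurrence radius.
#' @param config An [rqa_config()].
#' @return One-row tibble: `rr` (percent), `ent`, `ml`, `n_lines`.
#' @export
rqa_measures <- function(states, epsilon, config = rqa_config()) {
  if (!is.matrix(states)) states <- as_channel_matrix(states)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  s <- rqa_stream(states, epsilon, config$theiler, config$lmin, TRUE)
  hist_all <- s$hist  # entry i holds the count for line length i - 1
  keep <- which(hist_all > 0)
  hist <- tibble::tibble(length = keep - 1L,
                         count = as.integer(hist_all[keep]))
  rr <- 100 * s$recurrent / s$cells
  measures_from_histogram(hist, rr, config)
}

#' MdRQA measures from a materialized recurrence plot
#'
#' Full-matrix counterpart of [rqa_measures()]: computes RR over the
#' Theiler-excluded cells of the binary matrix and Ent/ML from
#' [diagonal_histogram()]. Used for verification and small plots.
#'
#' @param rp A `limb_rp` object (or binary matrix plus `config`).
#' @param config An [rqa_config()] (ignored when `rp` is a `limb_rp`).
#' @return One-row tibble: `rr`, `ent`, `ml`, `n_lines`.
#' @export
compute_measures <- function(rp, config = rqa_config()) {
  if (inherits(rp, "limb_rp")) {
    config <- rp$config
    mat <- rp$matrix
  } else {
    mat <- rp
  }
  off <- abs(row(mat) - col(mat)) >= config$theiler
  rr <- 100 * sum(mat[off]) / sum(off)
  measures_from_histogram(diagonal_histogram(mat, config), rr, config)
}

#' One-call MdRQA of a preprocessed session
#'
#' Embeds the standardized limb channels, calibrates the radius to
#' `target_rr` unless an explicit `epsilon` is given, and returns the
#' streaming measures together with the parameters used.
#'
#' @param ms Limb series from [preprocess_session()] (or channel matrix).
#' @param tau,m Embedding delay and per-channel dimension.
#' @param epsilon Recurrence radius; `NULL` calibrates to `target_rr`.
#' @param target_rr Target recurrence rate, percent (used when `epsilon` is
#'   `NULL`).
#' @param config An [rqa_config()].
#' @return One-row tibble: session metadata (when available), `rr`, `ent`,
#'   `ml`, `n_lines`, `epsilon`, `tau`, `m`.
#' @export
mdrqa <- function(ms, tau = 1, m = 14, epsilon = NULL, target_rr = 5,
                  config = rqa_config()) {
  st <- embed_multidim(ms, tau, m)
  if (is.null(epsilon))
    epsilon <- calibrate_radius(st, target_rr, theiler = config$theiler)
  out <- rqa_measures(st, epsilon, config)
  out$epsilon <- as.numeric(epsilon)
  out$tau <- as.integer(tau)
  out$m <- as.integer(m)
  meta <- attr(ms, "meta")
  if (!is.null(meta))
    out <- dplyr::bind_cols(tibble::as_tibble(meta[c("subject", "visit", "task")]),
                            out)
  out
}
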