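# Independent brute-force oracles, kept deliberately naive.

# Recurrence matrix by an explicit double loop over state pairs.
oracle_recurrence_matrix <- function(states, eps) {
  n <- nrow(states)
  r <- matrix(0L, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      r[i, j] <- as.integer(sqrt(sum((states[i, ] - states[j, ])^2)) <= eps)
  r
}

# Diagonal line histogram by scanning every diagonal cell by cell.
oracle_diag_hist <- function(r, lmin = 2, theiler = 1) {
  n <- nrow(r)
  lens <- integer(0)
  for (k in seq(-(n - 1), n - 1)) {
    if (abs(k) < theiler) next
    run <- 0L
    cells <- if (k >= 0) cbind(seq_len(n - k), seq_len(n - k) + k)
             else cbind(seq_len(n + k) - k, seq_len(n + k))
    for (q in seq_len(nrow(cells))) {
      if (r[cells[q, 1], cells[q, 2]] == 1) {
        run <- run + 1L
      } else {
        if (run >= lmin) lens <- c(lens, run)
        run <- 0L
      }
    }
    if (run >= lmin) lens <- c(lens, run)
  }
  lens
}

# RR / Ent / ML assembled purely from the oracle pieces above.
oracle_measures <- function(states, eps, lmin = 2, theiler = 1) {
  r <- oracle_recurrence_matrix(states, eps)
  n <- nrow(r)
  off <- abs(row(r) - col(r)) >= theiler
  rr <- 100 * sum(r[off]) / sum(off)
  lens <- oracle_diag_hist(r, lmin, theiler)
  if (length(lens) == 0) {
    ent <- 0; ml <- 0
  } else {
    p <- as.numeric(table(lens)) / length(lens)
    ent <- -sum(p * log(p))
    ml <- mean(lens)
  }
  list(rr = rr, ent = ent, ml = ml, n_lines = length(lens))
}

# Histogram-based mutual information, written independently of the package.
oracle_mi <- function(a, b, nb = 10) {
  ca <- cut(a, breaks = seq(min(a), max(a), length.out = nb + 1),
            include.lowest = TRUE)
  cb <- cut(b, breaks = seq(min(b), max(b), length.out = nb + 1),
            include.lowest = TRUE)
  tab <- table(ca, cb) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  s <- 0
  for (i in seq_len(nb)) for (j in seq_len(nb))
    if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  as.numeric(s)
}

# Small helpers for fixtures built in code.
sine_channels <- function(n = 1500, period = 40, d = 4, noise = 0,
                          phases = rep(0, d)) {
  t <- seq_len(n) - 1
  vapply(seq_len(d),
         function(i) sin(2 * pi * t / period + phases[i]) +
           if (noise > 0) rnorm(n, 0, noise) else 0,
         numeric(n))
}

tiny_session <- function(seed = 1, duration_s = 20, regime = "rhythmic",
                         regularity = 0.7, subject = "s01", visit = "T1",
                         task = if (regime == "rhythmic") "rattle" else "freeplay") {
  generate_session(subject, visit, task,
                   regime_params(regime, duration_s = duration_s,
                                 regularity = regularity), seed = seed)
}
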