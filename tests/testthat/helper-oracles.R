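# Independent brute-force oracles and small fixture builders used across
# the test files.  These deliberately share no code with the package
# implementations they check.

# Naive O(N^2) sample entropy by direct pair counting (triple loop),
# matching the package conventions: templates 1..N-m, self-matches
# excluded, max-norm, per-component tolerance.
naive_sample_entropy <- function(x, m, r, r_floor = 0, tol = NULL) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n <= m + 1L) return(NA_real_)
  if (is.null(tol)) tol <- pmax(r * apply(x, 2L, stats::sd), r_floor)
  tol[tol <= 0] <- .Machine$double.eps
  similar <- function(i, j, len) {
    for (t in 0:(len - 1L)) {
      if (any(abs(x[i + t, ] - x[j + t, ]) > tol)) return(FALSE)
    }
    TRUE
  }
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (similar(i, j, m)) {
        B <- B + 1L
        if (similar(i, j, m + 1L)) A <- A + 1L
      }
    }
  }
  if (B == 0L) return(NA_real_)
  if (A == 0L) return(log(B))
  -log(A / B)
}

# Direct discrete-sum DFT of one cycle (no fft), scaled by 1/n, returning
# components k = 1 and k = 2 as (re1, im1, re2, im2).
naive_fourier_descriptor <- function(row) {
  n <- length(row)
  out <- numeric(4L)
  for (k in 1:2) {
    acc <- 0 + 0i
    for (j in seq_len(n)) {
      acc <- acc + row[j] * exp(-2i * pi * k * (j - 1L) / n)
    }
    out[2L * k - 1L] <- Re(acc) / n
    out[2L * k] <- Im(acc) / n
  }
  out
}

# Per-sample open-quotient count oracle for one cycle.
naive_cycle_oq <- function(v, threshold_frac) {
  thr <- min(v) + threshold_frac * (max(v) - min(v))
  sum(v > thr) / length(v)
}

# Shrout-Fleiss ICC(2,k) via an explicit aov() decomposition -- an
# independent route to the package's direct mean-squares computation.
aov_icc2k <- function(scores) {
  df <- data.frame(
    y = as.vector(scores),
    rater = factor(rep(seq_len(nrow(scores)), ncol(scores))),
    target = factor(rep(seq_len(ncol(scores)), each = nrow(scores))))
  tab <- summary(stats::aov(y ~ rater + target, data = df))[[1L]]
  msj <- tab["rater", "Mean Sq"]
  msb <- tab["target", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- ncol(scores)
  (msb - mse) / (msb + (msj - mse) / n)
}

# A stationary EGG-like pulse train built directly from a closed-form
# pulse (independent of the package generator).
pulse_train <- function(fo = 220, fs = 20000, duration = 1, cq = 0.4,
                        amp = 1) {
  tt <- seq_len(round(duration * fs)) - 1L
  u <- (tt * fo / fs) %% 1
  a <- 0.3 * cq
  y <- numeric(length(u))
  y[u < a] <- 0.5 * (1 - cos(pi * u[u < a] / a))
  mid <- u >= a & u < cq
  y[mid] <- 0.5 * (1 + cos(pi * (u[mid] - a) / (cq - a)))
  egg_signal(amp * y, fs)
}

# Build a cycle_segmentation directly from known boundaries (bypassing
# detection) so that operators can be tested on hand-made signals.
manual_segmentation <- function(boundaries, fs, n_samples,
                                fo_min = 150, fo_max = 1200) {
  passaggio:::make_segmentation(boundaries, fs, 0, n_samples,
                                fo_min, fo_max, source = "manual")
}
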