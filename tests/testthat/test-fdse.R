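test_that("Fourier descriptors of closed-form cycles are exact", {
  n <- 64
  u <- (0:(n - 1)) / n
  # one cosine period across the cycle -> (0.5, 0, 0, 0)
  fd1 <- fourier_descriptors(matrix(cos(2 * pi * u), nrow = 1))
  expect_equal(as.numeric(fd1), c(0.5, 0, 0, 0), tolerance = 1e-12)
  # two periods -> energy only in component 2
  fd2 <- fourier_descriptors(matrix(cos(4 * pi * u), nrow = 1))
  expect_equal(as.numeric(fd2), c(0, 0, 0.5, 0), tolerance = 1e-12)
})

test_that("descriptors match a directly coded discrete-sum DFT", {
  n <- 64
  saw <- seq(-0.5, 0.5, length.out = n + 1)[-(n + 1)]
  set.seed(3)
  rows <- rbind(saw,
                rnorm(n),
                sin(2 * pi * (0:(n - 1)) / n) + 0.2 * rnorm(n))
  fds <- fourier_descriptors(rows)
  for (i in seq_len(nrow(rows))) {
    expect_equal(as.numeric(fds[i, ]), naive_fourier_descriptor(rows[i, ]),
                 tolerance = 1e-12)
  }
})

test_that("sample entropy handles the degenerate cases", {
  # perfectly repetitive series: conditional probability 1 -> entropy 0
  x <- matrix(rep(c(1, 2, 3), 20), ncol = 1)
  expect_equal(as.numeric(sample_entropy(x, m = 2, r = 0.2)), 0)
  # too short for any template pair
  short <- matrix(1:3, ncol = 1)
  v <- sample_entropy(short, m = 2, r = 0.2)
  expect_true(is.na(v))
  expect_true(attr(v, "undefined"))
})

test_that("sample entropy equals the brute-force pair-counting oracle", {
  set.seed(20)
  for (case in 1:30) {
    n <- sample(10:120, 1)
    d <- sample(1:4, 1)
    m <- sample(1:3, 1)
    x <- matrix(cumsum(rnorm(n * d)), ncol = d)
    got <- as.numeric(sample_entropy(x, m = m, r = 0.2))
    want <- naive_sample_entropy(x, m = m, r = 0.2)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(want)) expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("FDSE is invariant to overall EGG amplitude", {
  spec <- glide_spec(strategy = "smooth_oq_up", noise_sd = 0, seed = 9)
  eg <- synth_egg(spec)
  run <- function(egg) {
    seg <- detect_cycles(compute_degg(precondition_egg(egg)))
    fds <- fourier_descriptors(extract_cycles(egg, seg))
    fdse_cycle_trace(fds)$fdse_c
  }
  scaled <- eg$egg
  scaled$samples <- eg$egg$samples * 37.5
  expect_equal(run(eg$egg), run(scaled), tolerance = 1e-9)
})

test_that("entropy responds monotonically to descriptor noise", {
  base <- rep(c(0.3, -0.1, 0.2, 0.05), 50)   # periodic descriptor component
  noise_levels <- c(0, 0.002, 0.01, 0.05)
  meds <- sapply(noise_levels, function(ns) {
    median(sapply(1:10, function(s) {
      set.seed(s)
      x <- base + rnorm(length(base), 0, ns)
      as.numeric(sample_entropy(x, m = 2, r = 0.2, r_floor = 0.005))
    }))
  })
  expect_true(all(diff(meds) >= 0))
  expect_equal(meds[1], 0)
  expect_gt(meds[4], 0.5)
})

test_that("the cycle trace has one value per sliding block", {
  spec <- glide_spec(strategy = "stereotypical", seed = 2)
  eg <- synth_egg(spec)
  seg <- detect_cycles(compute_degg(precondition_egg(eg$egg)))
  fds <- fourier_descriptors(extract_cycles(eg$egg, seg))
  tr <- fdse_cycle_trace(fds, block_len = 40)
  expect_equal(nrow(tr), nrow(fds) - 40 + 1)
  # stationary shape: the trace is flat zero
  expect_true(all(tr$fdse_c == 0, na.rm = TRUE))
})

test_that("a 1 s phonation is scanned as 40 consecutive 25 ms segments", {
  spec <- glide_spec(strategy = "abrupt", noise_sd = 0.01, seed = 4)
  eg <- synth_egg(spec)
  seg <- detect_cycles(compute_degg(precondition_egg(eg$egg)))
  fds <- fourier_descriptors(extract_cycles(eg$egg, seg))
  ws <- fdse_windows(fdse_cycle_trace(fds), seg)
  expect_equal(nrow(ws$segments), 40L)
  expect_equal(nrow(ws$windows), 11L)
  expect_equal(ws$windows$window, -5:5)
  # windows sit on the contiguous 25 ms grid around window 0
  w0_start <- ws$windows$t_start[ws$windows$window == 0]
  ok <- !is.na(ws$windows$t_start)
  expect_equal(ws$windows$t_start[ok],
               w0_start + 0.025 * ws$windows$window[ok], tolerance = 1e-12)
  expect_equal(max_fdse_w(ws), max(ws$segments$fdse_w, na.rm = TRUE))
})

test_that("FDSE_w ties resolve to the earliest segment", {
  trace <- data.frame(cycle = 1:80, t_mid = seq(0.005, 0.995,
                                                length.out = 80),
                      fdse_c = rep(0.5, 80))
  class(trace) <- c("entropy_trace", "data.frame")
  seg <- list(t0 = 0, n_samples = 20000, fs = 20000)
  ws <- fdse_windows(trace, seg)
  expect_equal(ws$center_segment, 1L)
})

test_that("a window set centred near the signal edge flags clamped windows", {
  trace <- data.frame(cycle = 1:80,
                      t_mid = seq(0.005, 0.995, length.out = 80),
                      fdse_c = c(5, rep(0.1, 79)))
  class(trace) <- c("entropy_trace", "data.frame")
  seg <- list(t0 = 0, n_samples = 20000, fs = 20000)
  ws <- fdse_windows(trace, seg)
  expect_equal(ws$center_segment, 1L)
  expect_true(all(ws$windows$missing[ws$windows$window < 0]))
  expect_false(ws$windows$missing[ws$windows$window == 0])
})
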