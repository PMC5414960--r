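test_that("generators are bitwise-reproducible under a seed", {
  spec <- glide_spec(strategy = "abrupt", noise_sd = 0.02, seed = 17)
  a <- synth_egg(spec); b <- synth_egg(spec)
  expect_identical(a$egg$samples, b$egg$samples)
  expect_identical(a$truth$oq_per_cycle, b$truth$oq_per_cycle)
  fa <- synth_gaw_field(spec); fb <- synth_gaw_field(spec)
  expect_identical(fa$field$width, fb$field$width)
  ra <- synth_ratings(rep(1:5, 4), seed = 17)
  rb <- synth_ratings(rep(1:5, 4), seed = 17)
  expect_identical(ra$scores, rb$scores)
})

test_that("emitted ground truth is consistent with the emitted signals", {
  for (strategy in c("stereotypical", "smooth_oq_up", "smooth_oq_down",
                     "abrupt", "contact_loss")) {
    for (s in 1:3) {
      spec <- glide_spec(strategy = strategy, noise_sd = 0.01, seed = s)
      eg <- synth_egg(spec)
      # programmed boundaries delimit the emitted cycles
      expect_equal(length(eg$truth$boundaries), eg$truth$n_cycles + 1)
      expect_true(all(diff(eg$truth$boundaries) > 0))
      # detected cycle count matches programmed count within edge cycles;
      # cycles whose contacting slope is deliberately collapsed (contact
      # loss, break-burst amplitude drops) may legitimately evade the
      # dEGG detector
      seg <- detect_cycles(compute_degg(precondition_egg(eg$egg)))
      n_weak <- sum(eg$truth$amp_per_cycle < 1)
      expect_lte(sum(seg$valid), eg$truth$n_cycles + 2L)
      expect_gte(sum(seg$valid), eg$truth$n_cycles - n_weak - 2L)
      gf <- synth_gaw_field(spec)
      expect_equal(rowSums(gf$field$width), gf$gaw$samples)
    }
  }
})

test_that("fo endpoints and transition interval shape the phase track", {
  spec <- glide_spec(fo_start = 220, fo_end = 440, seed = 1,
                     strategy = "stereotypical")
  eg <- synth_egg(spec)
  fo <- eg$truth$fo_track
  expect_equal(fo[1], 220, tolerance = 1)
  expect_equal(fo[length(fo)], 440, tolerance = 1)
  # the change concentrates within the 50 ms transition interval
  tt <- (seq_along(fo) - 1) / spec$fs
  expect_lt(max(abs(fo[tt < 0.45] - 220)), 5)
  expect_lt(max(abs(fo[tt > 0.55] - 440)), 5)
})

test_that("contact-loss episodes mark cycles with no closed phase", {
  spec <- glide_spec(strategy = "contact_loss", noise_sd = 0.01, seed = 4)
  gf <- synth_gaw_field(spec)
  expect_gt(length(gf$truth$loss_cycles), 2L)
  # during loss cycles every position keeps width above the threshold
  b <- gf$truth$boundaries
  for (ci in gf$truth$loss_cycles[1:3]) {
    span <- ceiling(b[ci]):(ceiling(b[ci + 1]) - 1)
    expect_true(all(gf$field$width[span, ] > 0.5))
  }
})

test_that("rating tables reproduce the study dimensions and noise limits", {
  rt <- synth_ratings(rep(1:5, 4), n_raters = 12, seed = 1)
  expect_equal(dim(rt$scores), c(12L, 21L))  # 20 stimuli + 1 duplicate
  expect_equal(rt$duplicate_pair, c(1L, 21L))
  # zero noise, zero bias: perfect agreement
  perfect <- synth_ratings(rep(1:5, 4), rater_noise_sd = 0,
                           rater_bias_sd = 0, seed = 1)
  expect_equal(as.numeric(compute_icc(perfect)), 1)
  # overwhelming noise: agreement collapses
  iccs <- sapply(1:20, function(s)
    as.numeric(compute_icc(synth_ratings(rep(1:5, 4), rater_noise_sd = 25,
                                         rater_bias_sd = 0, seed = s))))
  expect_lt(median(iccs), 0.2)
})

test_that("pipeline severity separates the transition strategies", {
  strategies <- c("smooth_oq_up", "contact_loss", "abrupt")
  sev <- sapply(strategies, function(st) {
    vals <- sapply(1:10, function(s) {
      spec <- glide_spec(strategy = st, noise_sd = 0.01, seed = s)
      eg <- synth_egg(spec); gf <- synth_gaw_field(spec)
      r <- analyze_phonation(eg$egg, gf$gaw)
      c(r$max_fdse_w, r$oq$sd_delta_oq)
    })
    apply(vals, 1L, median)
  })
  # max FDSE_w strictly orders abrupt > contact loss > smooth
  expect_gt(sev[1, "abrupt"], sev[1, "contact_loss"])
  expect_gt(sev[1, "contact_loss"], sev[1, "smooth_oq_up"])
  # composite severity (product of both markers) preserves the order
  comp <- sev[1, ] * sev[2, ]
  expect_gt(comp["abrupt"], comp["contact_loss"])
  expect_gt(comp["contact_loss"], comp["smooth_oq_up"])
})
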