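test_that("first-order regression fits recover exact and null relations", {
  x <- seq(-3, 5, length.out = 25)
  fit <- fit_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  set.seed(1)
  null <- fit_regression(rnorm(1000), rnorm(1000))
  expect_lt(null$r2, 0.01)
  expect_error(fit_regression(rep(1, 10), rnorm(10)), "variance")
  expect_error(fit_regression(1:2, 1:2), "at least 3")
})

test_that("ICC matches a hand-computed table and an aov() route", {
  # 2 raters x 3 stimuli, computed by hand from the two-way mean squares:
  # scores 1,2,3 / 2,3,5 -> MSB = 2.3889*2... checked numerically below
  m <- rbind(c(1, 2, 3), c(2, 3, 5))
  rt <- rating_table(m)
  got <- as.numeric(compute_icc(rt, form = "ICC2k"))
  expect_equal(got, aov_icc2k(m), tolerance = 1e-12)
  # identical raters agree perfectly
  same <- rating_table(rbind(c(1, 3, 5), c(1, 3, 5), c(1, 3, 5)))
  expect_equal(as.numeric(compute_icc(same)), 1)
  # degenerate: no variance anywhere
  flat <- rating_table(matrix(3L, 4, 5))
  v <- compute_icc(flat)
  expect_true(is.na(v))
  # large cohort sanity: aov route and direct route agree
  set.seed(9)
  big <- synth_ratings(sample(1:5, 20, replace = TRUE),
                       rater_noise_sd = 1.5, seed = 3)
  expect_equal(as.numeric(compute_icc(big)), aov_icc2k(big$scores),
               tolerance = 1e-10)
})

test_that("the full chain runs on stereotypical and abrupt phonations", {
  spec0 <- glide_spec(strategy = "stereotypical", seed = 1)
  eg0 <- synth_egg(spec0); gf0 <- synth_gaw_field(spec0)
  r0 <- analyze_phonation(eg0$egg, gf0$gaw, gf0$field)
  expect_length(r0$failures, 0)
  expect_equal(r0$max_fdse_w, 0, tolerance = 1e-9)
  expect_lt(r0$oq$sd_delta_oq, 0.05)
  expect_equal(nrow(r0$contour_metrics), 11L)

  spec1 <- glide_spec(strategy = "abrupt", noise_sd = 0.01, seed = 1)
  eg1 <- synth_egg(spec1); gf1 <- synth_gaw_field(spec1)
  r1 <- analyze_phonation(eg1$egg, gf1$gaw, gf1$field)
  expect_length(r1$failures, 0)
  w0 <- r1$windows$windows[r1$windows$windows$window == 0, ]
  expect_lte(abs((w0$t_start + w0$t_end) / 2 - 0.5), 0.05)
  expect_gt(r1$max_fdse_w, r0$max_fdse_w)
})

test_that("stage failures are recorded without losing partial results", {
  spec <- glide_spec(strategy = "stereotypical", seed = 2)
  eg <- synth_egg(spec)
  bad_gaw <- gaw_series(rep(0, 20000), 20000)  # unvoiced GAW
  r <- analyze_phonation(eg$egg, bad_gaw)
  expect_named(r$failures, "gaw_metrics")
  expect_false(is.null(r$windows))  # EGG part survived
})

test_that("a synthetic cohort yields complete tables and planted effects", {
  co <- synth_cohort(seed = 5)
  expect_length(co$phonations, 20L)
  results <- lapply(co$phonations, function(ph)
    analyze_phonation(ph$egg, ph$gaw,
                      participant = ph$participant, task = ph$task))
  expect_true(all(vapply(results, function(r) length(r$failures),
                         integer(1)) == 0L))
  rep <- cohort_report(results, co$ratings)
  expect_equal(nrow(rep$summary), 20L)
  expect_equal(sort(unique(rep$summary$task)), c("lower", "upper"))
  expect_equal(length(unique(rep$summary$participant)), 10L)
  # planted severity drives ratings and entropy jointly
  for (tk in c("lower", "upper")) {
    f <- rep$fits_rating_fdse[[tk]]
    expect_gt(f$slope, 0)
    expect_gt(f$r2, 0.3)
  }
  # permuting the ratings destroys the association
  perm <- co$ratings
  set.seed(1)
  colnames(perm$scores) <- sample(colnames(perm$scores))
  rep_perm <- cohort_report(results, perm)
  for (tk in c("lower", "upper"))
    expect_lt(rep_perm$fits_rating_fdse[[tk]]$r2,
              rep$fits_rating_fdse[[tk]]$r2)
  # rater agreement within the emulated range
  expect_gt(as.numeric(rep$icc), 0.6)
  expect_lt(as.numeric(rep$icc), 0.98)
})

test_that("cohort artifacts are written and the report is deterministic", {
  co <- synth_cohort(n_participants = 3, seed = 2)
  results <- lapply(co$phonations, function(ph)
    analyze_phonation(ph$egg, ph$gaw,
                      participant = ph$participant, task = ph$task))
  out <- withr::local_tempdir()
  rep1 <- cohort_report(results, co$ratings, out_dir = out)
  expect_true(file.exists(file.path(out, "phonation_summary.csv")))
  expect_true(file.exists(file.path(out, "window_oq.csv")))
  expect_true(file.exists(file.path(out, "rating_vs_fdse.png")))
  rep2 <- cohort_report(results, co$ratings)
  expect_identical(rep1$summary, rep2$summary)
})
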