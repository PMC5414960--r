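# Orchestration and cohort statistics: the full per-phonation analysis
# chain, first-order polynomial regressions (r^2), the intraclass
# correlation of the perceptual ratings, and cohort summary tables.

#' Run the full analysis chain on one phonation
#'
#' EGG: high-pass preconditioning, dEGG, cycle detection, cycle-shape
#' Fourier descriptors, cycle- and window-based sample entropy and the
#' 11-window alignment centred on maximum FDSE_w. GAW (optional):
#' video-native cycle detection, per-cycle open quotient and per-window
#' OQ statistics over the EGG-aligned windows. Displacement field
#' (optional): spatio-temporal opening/closing contours per window and
#' their scalar descriptors. Stage failures are caught and recorded;
#' partial results are preserved.
#'
#' @param egg an [egg_signal].
#' @param gaw optional [gaw_series], time-aligned with the EGG.
#' @param field optional [displacement_field], time-aligned with the GAW.
#' @param config parameter list, see [default_config()].
#' @param participant,task optional identifiers carried into the result.
#' @return A `phonation_result`: list with `seg`, `trace`, `windows`,
#'   `max_fdse_w`, `oq` (`window_oq` or `NULL`), `contours`,
#'   `contour_metrics` (data.frame per window), `participant`, `task`,
#'   `failures` (named character vector of stage error messages).
#' @export
analyze_phonation <- function(egg, gaw = NULL, field = NULL,
                              config = default_config(),
                              participant = NA_character_,
                              task = NA_character_) {
  cfg <- utils::modifyList(default_config(), config)
  res <- list(participant = participant, task = task,
              failures = character(0))
  class(res) <- "phonation_result"
  fail <- function(stage, e) {
    res$failures[stage] <<- conditionMessage(e)
    NULL
  }
  res$seg <- tryCatch({
    pre <- precondition_egg(egg, cfg$highpass_hz)
    degg <- compute_degg(pre, cfg$smoothing_len)
    detect_cycles(degg, cfg$fo_min, cfg$fo_max)
  }, error = function(e) fail("egg_cycles", e))
  if (is.null(res$seg)) return(res)
  res$windows <- tryCatch({
    cycles <- extract_cycles(egg, res$seg, cfg$n_resample)
    fds <- fourier_descriptors(cycles)
    res$trace <- fdse_cycle_trace(fds, m = cfg$samp_en_m, r = cfg$samp_en_r,
                                  r_floor = cfg$samp_en_floor,
                                  block_len = cfg$block_len)
    fdse_windows(res$trace, res$seg, cfg$window_len)
  }, error = function(e) fail("fdse", e))
  if (is.null(res$windows)) return(res)
  res$max_fdse_w <- max_fdse_w(res$windows)
  if (!is.null(gaw)) {
    res$oq <- tryCatch({
      gseg <- gaw_cycles(gaw, cfg$fo_min, cfg$fo_max)
      oq <- open_quotient(gaw, gseg, cfg$open_threshold_frac)
      window_oq(oq, res$windows)
    }, error = function(e) fail("gaw_metrics", e))
    if (!is.null(field)) {
      res$contours <- tryCatch({
        gseg <- gaw_cycles(gaw, cfg$fo_min, cfg$fo_max)
        inst <- local_open_close_instants(field, gseg,
                                          cfg$contour_threshold)
        normalize_and_average(inst, res$windows)
      }, error = function(e) fail("glottal_dynamics", e))
      if (!is.null(res$contours)) {
        cm <- do.call(rbind, lapply(res$contours, contour_summary_metrics))
        cm$window <- res$windows$windows$window
        res$contour_metrics <- cm
      }
    }
  }
  res
}

#' @export
print.phonation_result <- function(x, ...) {
  cat(sprintf("<phonation_result> %s/%s: max FDSE_w = %s, SD(delta OQ) = %s%s\n",
              x$participant, x$task,
              if (is.null(x$max_fdse_w)) "?" else sprintf("%.4g", x$max_fdse_w),
              if (is.null(x$oq)) "?" else sprintf("%.4g", x$oq$sd_delta_oq),
              if (length(x$failures))
                paste0(" [failed: ", paste(names(x$failures), collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' First-order polynomial regression fit
#'
#' Least-squares line with `r2` the squared Pearson correlation.
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite).
#' @return A `regression_fit`: list with `slope`, `intercept`, `r2`, `n`.
#' @export
fit_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite (x, y) pairs")
  if (stats::sd(x) == 0) stop("zero variance in x: fit undefined")
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = stats::cor(x, y)^2, n = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.4g x + %.4g, r^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Intraclass correlation coefficient of a rating table
#'
#' Two-way ANOVA-based ICC in the Shrout-Fleiss framework, computed from
#' the mean squares of the rater-by-stimulus matrix. The default form is
#' ICC(2,k): two-way random effects, absolute agreement, average of the k
#' raters.
#'
#' @param rt a [rating_table].
#' @param form `"ICC2k"` (default), `"ICC2_1"` (single rater, absolute
#'   agreement) or `"ICC3k"` (two-way mixed, consistency, average
#'   measures).
#' @return ICC value in \[-1, 1\] with attribute `form`; `NA` with
#'   attribute `undefined = TRUE` when the between-stimulus variance is
#'   degenerate.
#' @export
compute_icc <- function(rt, form = c("ICC2k", "ICC2_1", "ICC3k")) {
  form <- match.arg(form)
  stopifnot(inherits(rt, "rating_table"))
  x <- rt$scores             # raters (k) x stimuli/targets (n)
  k <- nrow(x); n <- ncol(x)
  grand <- mean(x)
  target_means <- colMeans(x)
  rater_means <- rowMeans(x)
  ss_total <- sum((x - grand)^2)
  ss_target <- k * sum((target_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_err <- ss_total - ss_target - ss_rater
  msb <- ss_target / (n - 1)                 # between targets
  msj <- ss_rater / (k - 1)                  # between raters
  mse <- ss_err / ((n - 1) * (k - 1))        # residual
  if (msb <= .Machine$double.eps && mse <= .Machine$double.eps)
    return(structure(NA_real_, undefined = TRUE, form = form))
  val <- switch(form,
    ICC2k = (msb - mse) / (msb + (msj - mse) / n),
    ICC2_1 = (msb - mse) /
      (msb + (k - 1) * mse + k * (msj - mse) / n),
    ICC3k = (msb - mse) / msb)
  structure(val, form = form)
}

#' Cohort summary tables, regressions and figures
#'
#' Builds the per-phonation summary (maximum FDSE_w, SD of the
#' between-window OQ differences), merges the per-stimulus rating
#' aggregate, and fits per task (a) perceptual rating versus maximum
#' FDSE_w and (b) SD(delta OQ) versus maximum FDSE_w. Also assembles the
#' long-format per-window OQ table underlying the window boxplots.
#' Optionally writes CSV tables and PNG figures.
#'
#' @param results list of `phonation_result` objects.
#' @param ratings a [rating_table] whose stimulus (column) names match
#'   `"<participant>_<task>"` of the results.
#' @param out_dir optional output directory for CSV/PNG artifacts.
#' @param rating_aggregate `"mean"` (default) or `"median"` across raters.
#' @return A `cohort_report`: list with `summary` (data.frame),
#'   `fits_rating_fdse`, `fits_fdse_oqvar` (per-task `regression_fit` or
#'   `NULL` with a notice when < 3 complete phonations), `window_oq_long`
#'   (data.frame), `icc`, `notices` (character).
#' @export
cohort_report <- function(results, ratings, out_dir = NULL,
                          rating_aggregate = c("mean", "median")) {
  rating_aggregate <- match.arg(rating_aggregate)
  agg_fun <- if (rating_aggregate == "mean") mean else stats::median
  summary_df <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      participant = r$participant, task = r$task,
      stimulus = sprintf("%s_%s", r$participant, r$task),
      max_fdse_w = r$max_fdse_w %||% NA_real_,
      sd_delta_oq = if (is.null(r$oq)) NA_real_ else r$oq$sd_delta_oq,
      n_failures = length(r$failures))
  }))
  rownames(summary_df) <- NULL
  stim_rating <- apply(ratings$scores, 2L, agg_fun)
  summary_df$rating <- stim_rating[summary_df$stimulus]
  window_oq_long <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$oq)) return(NULL)
    cbind(data.frame(participant = r$participant, task = r$task),
          r$oq$oq_per_window)
  }))
  rownames(window_oq_long) <- NULL
  notices <- character(0)
  fit_task <- function(df, xcol, ycol) {
    fits <- list()
    for (tk in unique(df$task)) {
      sub <- df[df$task == tk & is.finite(df[[xcol]]) &
                  is.finite(df[[ycol]]), ]
      if (nrow(sub) < 3L) {
        notices <<- c(notices, sprintf(
          "task %s: only %d complete phonation(s) for %s ~ %s; regression skipped",
          tk, nrow(sub), ycol, xcol))
        fits[[tk]] <- NULL
      } else {
        fits[[tk]] <- tryCatch(
          fit_regression(sub[[xcol]], sub[[ycol]]),
          error = function(e) {
            notices <<- c(notices, sprintf("task %s: %s ~ %s: %s",
                                           tk, ycol, xcol,
                                           conditionMessage(e)))
            NULL
          })
      }
    }
    fits
  }
  fits_rating_fdse <- fit_task(summary_df, "rating", "max_fdse_w")
  fits_fdse_oqvar <- fit_task(summary_df, "sd_delta_oq", "max_fdse_w")
  icc <- compute_icc(ratings)
  out <- list(summary = summary_df,
              fits_rating_fdse = fits_rating_fdse,
              fits_fdse_oqvar = fits_fdse_oqvar,
              window_oq_long = window_oq_long,
              icc = icc, notices = notices)
  class(out) <- "cohort_report"
  if (!is.null(out_dir)) write_cohort_artifacts(out, out_dir)
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d phonations, ICC(%s) = %.3f\n",
              nrow(x$summary), attr(x$icc, "form"), x$icc))
  for (tk in names(x$fits_rating_fdse))
    if (!is.null(x$fits_rating_fdse[[tk]]))
      cat(sprintf("  %s: r^2(rating, max FDSE_w) = %.3f\n",
                  tk, x$fits_rating_fdse[[tk]]$r2))
  for (tk in names(x$fits_fdse_oqvar))
    if (!is.null(x$fits_fdse_oqvar[[tk]]))
      cat(sprintf("  %s: r^2(SD delta OQ, max FDSE_w) = %.3f\n",
                  tk, x$fits_fdse_oqvar[[tk]]$r2))
  invisible(x)
}

write_cohort_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary,
                   file.path(out_dir, "phonation_summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$window_oq_long))
    utils::write.csv(report$window_oq_long,
                     file.path(out_dir, "window_oq.csv"), row.names = FALSE)
  plot_one <- function(file, xcol, ycol, fits, xlab, ylab) {
    grDevices::png(file.path(out_dir, file), width = 900, height = 450)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, length(unique(report$summary$task))))
    for (tk in unique(report$summary$task)) {
      sub <- report$summary[report$summary$task == tk, ]
      graphics::plot(sub[[xcol]], sub[[ycol]], pch = 19,
                     xlab = xlab, ylab = ylab, main = sprintf("task: %s", tk))
      f <- fits[[tk]]
      if (!is.null(f)) {
        graphics::abline(f$intercept, f$slope, col = "grey40")
        graphics::legend("topleft", bty = "n", legend = sprintf(
          "y = %.3g x + %.3g, r2 = %.2f", f$slope, f$intercept, f$r2))
      }
    }
  }
  plot_one("rating_vs_fdse.png", "rating", "max_fdse_w",
           report$fits_rating_fdse, "perceptual rating", "max FDSE_w")
  plot_one("fdse_vs_oqvar.png", "sd_delta_oq", "max_fdse_w",
           report$fits_fdse_oqvar, "SD(delta OQ)", "max FDSE_w")
  if (!is.null(report$window_oq_long)) {
    grDevices::png(file.path(out_dir, "oq_per_window.png"),
                   width = 900, height = 450)
    graphics::par(mfrow = c(1, length(unique(report$window_oq_long$task))))
    for (tk in unique(report$window_oq_long$task)) {
      sub <- report$window_oq_long[report$window_oq_long$task == tk, ]
      graphics::boxplot(oq_mean ~ window, data = sub,
                        xlab = "analysis window", ylab = "OQ (GAW)",
                        main = sprintf("task: %s", tk))
    }
    grDevices::dev.off()
  }
  invisible(out_dir)
}
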