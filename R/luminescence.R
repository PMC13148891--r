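# Split-luciferase readout analysis: lytic-assay titration (log10 RLU,
# background subtraction, dilution scaling) and live-cell kinetics
# (per-well baseline normalization, plateau characterization, treatment
# fold-changes, dose proportionality, RLU-editing correlation).

#' Per-well baseline normalization of luminescence time courses
#'
#' Divides every reading of a well by that well's pre-treatment baseline
#' (the reading at `baseline_time`, conventionally -1 h; time 0 is
#' treatment addition), removing well-to-well scale differences. Wells with
#' a non-positive or missing baseline are excluded and flagged. Per-time
#' mean and SD are summarized within each condition.
#'
#' @param wells long-format data.frame with columns `well`, `condition`,
#'   `time_h`, `rlu`
#' @param baseline_time the pre-treatment time point (default -1 h)
#' @return `timecourse` object: `wells` (normalized long data, column
#'   `norm`), `summary` (condition x time mean/sd/n), `baseline_time`,
#'   `excluded` (well ids dropped)
#' @export
normalize_wells <- function(wells, baseline_time = -1) {
  stopifnot(all(c("well", "condition", "time_h", "rlu") %in% names(wells)))
  parts <- split(wells, wells$well)
  excluded <- character(0)
  out <- lapply(parts, function(w) {
    w <- w[order(w$time_h), , drop = FALSE]
    i <- which(w$time_h == baseline_time)
    if (length(i) != 1 || !is.finite(w$rlu[i]) || w$rlu[i] <= 0) {
      excluded <<- c(excluded, w$well[1])
      return(NULL)
    }
    w$norm <- w$rlu / w$rlu[i]
    w
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0)
    stop("no well has a positive baseline at time ", baseline_time)
  rownames(out) <- NULL
  agg <- stats::aggregate(norm ~ condition + time_h, data = out,
                          FUN = function(v) c(mean = mean(v),
                                              sd = if (length(v) > 1)
                                                stats::sd(v) else 0,
                                              n = length(v)))
  summary <- data.frame(condition = agg$condition, time_h = agg$time_h,
                        mean = agg$norm[, "mean"], sd = agg$norm[, "sd"],
                        n = agg$norm[, "n"], stringsAsFactors = FALSE)
  summary <- summary[order(summary$condition, summary$time_h), ]
  rownames(summary) <- NULL
  structure(list(wells = out, summary = summary,
                 baseline_time = baseline_time, excluded = excluded),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %d wells, %d conditions, t in [%g, %g] h\n",
              length(unique(x$wells$well)),
              length(unique(x$wells$condition)),
              min(x$wells$time_h), max(x$wells$time_h)))
  if (length(x$excluded))
    cat("  excluded wells:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

tc_mean_curve <- function(tc, condition = NULL, from_time = 0) {
  s <- tc$summary
  if (!is.null(condition)) s <- s[s$condition == condition, , drop = FALSE]
  if (length(unique(s$condition)) > 1)
    stop("time course has several conditions; pass 'condition'")
  s <- s[s$time_h >= from_time, , drop = FALSE]
  s[order(s$time_h), , drop = FALSE]
}

#' Characterize the kinetics of a normalized time course
#'
#' Finds the peak of the mean curve and the plateau time: the earliest time
#' point from which every later mean value stays within a relative
#' `plateau_tolerance` band around the mean of the final `window` hours. If
#' the band is never entered the course is flagged censored (e.g., a still
#' rising signal).
#'
#' @param tc a [normalize_wells()] result
#' @param condition condition to summarize (required if several present)
#' @param plateau_tolerance relative half-width of the plateau band
#'   (default 0.05)
#' @param window width in hours of the final window defining the plateau
#'   level (default 1)
#' @return `kinetics_summary`: `peak`, `peak_time`, `plateau_time`,
#'   `plateau_level`, `censored`, `flags`
#' @export
summarize_kinetics <- function(tc, condition = NULL,
                               plateau_tolerance = 0.05, window = 1.0) {
  stopifnot(inherits(tc, "timecourse"))
  s <- tc_mean_curve(tc, condition)
  if (nrow(s) < 4 || diff(range(s$time_h)) < 2)
    stop("need at least 4 post-treatment time points spanning >= 2 h")
  t_end <- max(s$time_h)
  final <- s$mean[s$time_h > t_end - window]
  level <- mean(final)
  within <- abs(s$mean - level) <= plateau_tolerance * abs(level)
  # earliest index from which all later points sit inside the band; the
  # band must be sustained for at least the final window, so a curve that
  # only enters it inside that window (e.g. a monotone ramp) is censored
  ok_from <- rev(cumprod(rev(within))) == 1 & s$time_h <= t_end - window
  plateau_time <- if (any(ok_from)) s$time_h[which(ok_from)[1]] else NA_real_
  structure(list(peak = max(s$mean), peak_time = s$time_h[which.max(s$mean)],
                 plateau_time = plateau_time, plateau_level = level,
                 censored = is.na(plateau_time),
                 flags = if (is.na(plateau_time)) "censored" else character(0)),
            class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf("<kinetics> peak %.3g at %.2g h; plateau %s (level %.3g)%s\n",
              x$peak, x$peak_time,
              if (x$censored) "not reached" else sprintf("at %.2g h",
                                                         x$plateau_time),
              x$plateau_level, if (x$censored) " [censored]" else ""))
  invisible(x)
}

tc_at_time <- function(tc, condition, t) {
  s <- tc_mean_curve(tc, condition, from_time = -Inf)
  i <- which.min(abs(s$time_h - t))
  dt <- abs(s$time_h[i] - t)
  gaps <- diff(sort(unique(s$time_h)))
  local_gap <- if (length(gaps)) min(gaps[pmax(i - 1, 1):pmin(i, length(gaps))])
               else Inf
  if (dt > local_gap / 2)
    stop(sprintf("no time point within half a sampling interval of t = %g h", t))
  s[i, , drop = FALSE]
}

#' Fold change of a control course over a treated course
#'
#' Ratio of the control mean to the treated mean at time `t` (nearest
#' recorded point within half the local sampling interval; no
#' interpolation). Values above 1 read as a reduction by treatment, so a
#' 4-fold inhibition returns 4.0. SD is propagated from both courses.
#'
#' @param treated,control [normalize_wells()] results (single-condition, or
#'   pass `treated_condition`/`control_condition`)
#' @param t time in hours at which to compare
#' @param treated_condition,control_condition condition labels when the
#'   course objects hold several conditions
#' @return list with `ratio`, `sd`, `t_used`, `infinite` (TRUE when the
#'   treated mean is 0)
#' @export
fold_change <- function(treated, control, t,
                        treated_condition = NULL, control_condition = NULL) {
  tr <- tc_at_time(treated, treated_condition, t)
  co <- tc_at_time(control, control_condition, t)
  if (tr$mean == 0) {
    return(list(ratio = Inf, sd = NA_real_, t_used = tr$time_h,
                infinite = TRUE))
  }
  ratio <- co$mean / tr$mean
  rel <- sqrt((co$sd / co$mean)^2 + (tr$sd / tr$mean)^2)
  list(ratio = ratio, sd = abs(ratio) * rel, t_used = tr$time_h,
       infinite = FALSE)
}

#' Dose-proportionality report at one time point
#'
#' For each dose, the ratio of its mean signal to the smallest dose's is
#' compared with the volume ratio; a dose is proportional when the observed
#' ratio is within `tolerance` of the expected one, and flagged saturating
#' when it falls short beyond that.
#'
#' @param tc a [normalize_wells()] result holding one condition per dose
#' @param doses named numeric vector: condition label -> dose volume (uL)
#' @param t time in hours at which to compare
#' @param tolerance relative tolerance on ratio/expected (default 0.3)
#' @return data.frame with `condition`, `volume_ul`, `mean`, `ratio`,
#'   `expected`, `proportional`, `saturating`
#' @export
dose_linearity <- function(tc, doses, t, tolerance = 0.3) {
  if (length(doses) < 2) stop("need at least 2 doses")
  ref <- names(doses)[which.min(doses)]
  rows <- lapply(names(doses), function(cond) {
    s <- tc_at_time(tc, cond, t)
    data.frame(condition = cond, volume_ul = unname(doses[cond]),
               mean = s$mean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ref_mean <- out$mean[out$condition == ref]
  if (ref_mean == 0) stop("smallest dose has zero mean signal")
  out$ratio <- out$mean / ref_mean
  out$expected <- out$volume_ul / min(doses)
  rel <- out$ratio / out$expected - 1
  out$proportional <- abs(rel) <= tolerance
  out$saturating <- rel < -tolerance
  out[order(out$volume_ul), ]
}

#' Correlate editing efficiency with log10 luminescence
#'
#' Ordinary least squares of editing percentage (response) on log10 RLU
#' (predictor), as used to relate the live-cell luminescence readout to the
#' editing outcome it predicts.
#'
#' @param points data.frame with columns `log10_rlu` and `editing_pct`
#' @return `correlation_result`: `slope`, `intercept`, `r_squared`, `n`
#' @export
correlate_editing <- function(points) {
  stopifnot(all(c("log10_rlu", "editing_pct") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("log10_rlu",
                                                    "editing_pct")]), ]
  if (nrow(points) < 3) stop("need at least 3 complete points")
  if (stats::sd(points$log10_rlu) == 0)
    stop("log10 RLU has zero variance; correlation undefined")
  fit <- stats::lm(editing_pct ~ log10_rlu, data = points)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # collinear input is fine
  structure(list(slope = unname(stats::coef(fit)[["log10_rlu"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 r_squared = r2, n = nrow(points)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation> editing%% = %.3g * log10(RLU) + %.3g | R^2 = %.4f | n = %d\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Lytic-assay titer summary
#'
#' Summarizes replicate lytic-assay readings of one sample: mean and SD of
#' log10 RLU, and a background-subtracted linear value scaled back to the
#' undiluted preparation (per uL) for cross-prep comparison. Background
#' (e.g., PBS wells on the same plate) is mean-subtracted in linear space;
#' samples below background floor at 0 with a flag. Non-positive readings
#' are excluded from the log summary (log undefined) with a flag.
#'
#' @param rlu replicate RLU readings of the sample
#' @param background RLU readings of the background wells (default 0)
#' @param dilution fold dilution at which the sample was measured
#'   (default 1 = undiluted)
#' @return list with `log10_mean`, `log10_sd`, `rlu_mean`,
#'   `rlu_minus_background`, `per_ul_undiluted`, `n`, `flags`
#' @export
lytic_titer <- function(rlu, background = 0, dilution = 1) {
  if (length(rlu) < 1) stop("need at least one replicate")
  if (dilution < 1) stop("'dilution' must be >= 1")
  flags <- character(0)
  pos <- rlu[is.finite(rlu) & rlu > 0]
  if (length(pos) < length(rlu)) flags <- c(flags, "nonpositive_excluded")
  if (length(pos) == 0) stop("no positive RLU readings")
  bg <- mean(background)
  sub <- mean(pos) - bg
  if (sub < 0) {
    sub <- 0
    flags <- c(flags, "below_background")
  }
  list(log10_mean = mean(log10(pos)),
       log10_sd = if (length(pos) > 1) stats::sd(log10(pos)) else 0,
       rlu_mean = mean(pos), rlu_minus_background = sub,
       per_ul_undiluted = sub * dilution, n = length(pos), flags = flags)
}
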