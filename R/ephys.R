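#' Detect the onset of an evoked fEPSP
#'
#' Baseline mean and sd are taken over `baseline_window` (default: trace
#' start to the stimulus); the onset is the first post-stimulus time (after
#' a short artifact blanking window) at which the voltage deviates from the
#' baseline mean by more than `multiplier` baseline sds continuously for at
#' least `dwell_ms`.
#'
#' @param w a [waveform()].
#' @param baseline_window `c(from, to)` ms; default `c(t0, stimulus)`.
#' @param multiplier threshold in baseline sds (default 3).
#' @param dwell_ms minimum supra-threshold duration (default 0.5 ms).
#' @param blank_ms stimulus-artifact blanking after the stimulus.
#' @return Onset time, ms. Errors with class `no_event` when no sustained
#'   crossing exists.
#' @export
detect_onset <- function(w, baseline_window = NULL, multiplier = 3,
                         dwell_ms = 0.5, blank_ms = 1) {
  stim <- wf_attr(w, "stimulus_ms")
  if (is.null(baseline_window)) baseline_window <- c(w$time_ms[1], stim)
  bl <- w$voltage_mV[w$time_ms >= baseline_window[1] &
                       w$time_ms < baseline_window[2]]
  if (length(bl) < 2) stopf("parameter_error", "baseline window too short")
  bmean <- mean(bl)
  bsd <- sd(bl)
  thr <- multiplier * bsd
  dt <- w$time_ms[2] - w$time_ms[1]
  need <- max(1L, ceiling(dwell_ms / dt))
  idx <- which(w$time_ms >= stim + blank_ms)
  dev <- abs(w$voltage_mV[idx] - bmean) > thr
  run <- 0L
  for (i in seq_along(dev)) {
    run <- if (dev[i]) run + 1L else 0L
    if (run >= need) return(w$time_ms[idx[i - need + 1L]])
  }
  stopf("no_event", "no event detected (threshold %.4g mV sustained %g ms)",
        thr, dwell_ms)
}

#' Split a waveform at its extremum into rise and decay segments
#'
#' The extremum is the most negative voltage after the onset; the rise
#' segment spans `[onset, extremum]`, the decay segment
#' `[extremum, end]`, sharing the extremum sample. If the extremum falls on
#' the last sample the decay is truncated: a warning is issued and no decay
#' segment is returned.
#'
#' @param w a [waveform()].
#' @param onset onset time from [detect_onset()].
#' @return list(`rise`, `decay`, `extremum_ms`, `extremum_mV`); `decay` is
#'   `NULL` when truncated.
#' @export
split_at_extremum <- function(w, onset) {
  idx <- which(w$time_ms >= onset)
  if (length(idx) < 2) stopf("parameter_error", "no samples after onset")
  ext_rel <- which.min(w$voltage_mV[idx])
  ext <- idx[ext_rel]
  rise <- data.frame(time_ms = w$time_ms[idx[1]:ext],
                     voltage_mV = w$voltage_mV[idx[1]:ext])
  if (ext == length(w$time_ms)) {
    warning("extremum at trace end: decay truncated, decay fit refused",
            call. = FALSE)
    decay <- NULL
  } else {
    decay <- data.frame(time_ms = w$time_ms[ext:length(w$time_ms)],
                        voltage_mV = w$voltage_mV[ext:length(w$time_ms)])
  }
  list(rise = rise, decay = decay, extremum_ms = w$time_ms[ext],
       extremum_mV = w$voltage_mV[ext])
}

#' Boltzmann sigmoid
#'
#' `B(t) = A2 + (A1 - A2) / (1 + exp((t - t50) / k))`: plateau `A1` early,
#' `A2` late, half-transition at `t50` (where `B(t50) = (A1 + A2)/2`),
#' slope factor `k > 0`.
#'
#' @param t time, ms.
#' @param A1,A2,t50,k parameters.
#' @export
boltzmann <- function(t, A1, A2, t50, k) {
  A2 + (A1 - A2) / (1 + exp((t - t50) / k))
}

#' Closed-form inversion of the Boltzmann sigmoid
#' @param fit a `boltzmann_fit` (or list with A1, A2, t50, k).
#' @param y level to invert, strictly between A1 and A2.
#' @return t such that `B(t) = y`.
#' @export
boltzmann_inverse <- function(fit, y) {
  ratio <- (y - fit$A1) / (fit$A2 - y)
  if (!is.finite(ratio) || ratio <= 0) {
    stopf("parameter_out_of_range",
          "level %.4g outside the fitted range (%.4g, %.4g)", y, fit$A1,
          fit$A2)
  }
  fit$t50 + fit$k * log(ratio)
}

#' Fit a Boltzmann sigmoid to a monotone fEPSP segment
#'
#' Levenberg-Marquardt least squares with endpoint-based initialization
#' (`A1` = first sample, `A2` = last sample, `t50` = mid-level crossing,
#' `k` = duration/10) and up to 5 deterministically jittered restarts.
#' The fit is box-constrained: `t50` must lie within the segment's time
#' span and the plateaus within 1.5x the segment's voltage range. Without
#' these bounds a segment cut at the event onset (whose sigmoidal foot is
#' outside the window) lets the early plateau drift to unphysical values.
#'
#' @param segment data.frame with `time_ms`, `voltage_mV` (>= 8 samples).
#' @param label `"rise"` or `"decay"` (metadata only).
#' @return A list of class `boltzmann_fit`: A1, A2, t50, k, rms, segment.
#' @export
fit_boltzmann <- function(segment, label = c("rise", "decay")) {
  label <- match.arg(label)
  t <- segment$time_ms
  v <- segment$voltage_mV
  if (length(t) < 8) {
    stopf("fit_failure", "segment has %d < 8 samples", length(t))
  }
  if (diff(range(v)) == 0) {
    stopf("fit_failure", "constant segment cannot be fitted")
  }
  A1_0 <- v[1]
  A2_0 <- v[length(v)]
  mid <- (A1_0 + A2_0) / 2
  cross <- which.min(abs(v - mid))
  t50_0 <- t[cross]
  k_0 <- (t[length(t)] - t[1]) / 10
  jit <- rbind(c(1, 1, 1, 1),
               c(1, 1, 1, 0.5), c(1, 1, 1, 2),
               c(1.05, 0.95, 0.98, 1), c(0.95, 1.05, 1.02, 3))
  span <- diff(range(v))
  vlo <- min(v) - 0.5 * span
  vhi <- max(v) + 0.5 * span
  lower <- c(A1 = vlo, A2 = vlo, t50 = t[1], k = 1e-6)
  upper <- c(A1 = vhi, A2 = vhi, t50 = t[length(t)], k = Inf)
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  last_err <- NULL
  for (r in seq_len(nrow(jit))) {
    st <- c(A1 = clamp(A1_0 * jit[r, 1], vlo, vhi),
            A2 = clamp(A2_0 * jit[r, 2], vlo, vhi),
            t50 = clamp(t50_0 * jit[r, 3], t[1], t[length(t)]),
            k = max(k_0 * jit[r, 4], 1e-3))
    resid_fn <- function(par) {
      v - boltzmann(t, par[1], par[2], par[3], par[4])
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) e)
    ok <- !inherits(fit, "error") && fit$info %in% 1:4
    if (ok) {
      cf <- fit$par
      return(structure(list(A1 = unname(cf[1]), A2 = unname(cf[2]),
                            t50 = unname(cf[3]), k = unname(cf[4]),
                            rms = sqrt(mean(fit$fvec^2)), segment = label),
                       class = "boltzmann_fit"))
    }
    last_err <- if (inherits(fit, "error")) fit else
      simpleError(fit$message)
  }
  stopf("fit_failure", "Boltzmann fit did not converge after %d restarts: %s",
        nrow(jit), conditionMessage(last_err))
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit:%s> A1=%.4g A2=%.4g t50=%.4g ms k=%.4g ms rms=%.3g\n",
    x$segment, x$A1, x$A2, x$t50, x$k, x$rms))
  invisible(x)
}

#' Trapezoidal area under |voltage - baseline| over a window
#'
#' Boundary samples are linearly interpolated so the window limits are
#' honored exactly.
#'
#' @param w a [waveform()].
#' @param from,to window limits, ms.
#' @param baseline baseline voltage, mV.
#' @return Area, mV*ms (magnitude).
#' @export
auc_trapezoid <- function(w, from, to, baseline = 0) {
  t <- w$time_ms
  v <- abs(w$voltage_mV - baseline)
  if (from < t[1] || to > t[length(t)]) {
    stopf("parameter_error", "AUC window outside the trace")
  }
  vf <- stats::approx(t, v, xout = from)$y
  vt <- stats::approx(t, v, xout = to)$y
  inside <- which(t > from & t < to)
  tt <- c(from, t[inside], to)
  vv <- c(vf, v[inside], vt)
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
}

#' Derive fEPSP parameters from the fitted rise and decay
#'
#' Peak = late plateau `A2` of the rising fit (signed mV). Rise time =
#' time after onset at which the fitted rise reaches 67% of the peak
#' (closed-form inversion). Decay time = time after the extremum at which
#' the fitted decay returns to 33% of the peak (this mirror of the 67%
#' rise criterion is a convention of this package; the decay criterion is
#' not standardized). AUC = trapezoidal integral of the baseline-subtracted
#' magnitude over `[onset, onset + auc_window]`.
#'
#' @param rise_fit,decay_fit `boltzmann_fit` objects (`decay_fit` may be
#'   `NULL`: decay time is then `NA`).
#' @param w the analyzed [waveform()].
#' @param onset onset time, ms.
#' @param extremum_ms time of the peak sample (needed for decay time).
#' @param baseline baseline voltage, mV.
#' @param auc_window AUC window, ms (default 30).
#' @param rise_fraction fraction of peak defining the rise time.
#' @return A list of class `fepsp_params`: `peak_mV`, `rise_time_ms`,
#'   `decay_time_ms`, `auc_mVms`, `onset_ms`, `condition`.
#' @export
compute_params <- function(rise_fit, decay_fit, w, onset,
                           extremum_ms = NULL, baseline = 0,
                           auc_window = 30, rise_fraction = 0.67) {
  peak <- rise_fit$A2
  y67 <- rise_fit$A1 + rise_fraction * (peak - rise_fit$A1)
  t67 <- boltzmann_inverse(rise_fit, y67)
  rise_time <- t67 - onset
  decay_time <- NA_real_
  if (!is.null(decay_fit)) {
    y33 <- rise_fit$A1 + (1 - rise_fraction) * (peak - rise_fit$A1)
    ok <- (y33 - decay_fit$A1) / (decay_fit$A2 - y33)
    if (is.finite(ok) && ok > 0) {
      ref <- extremum_ms %||% decay_fit$t50
      decay_time <- boltzmann_inverse(decay_fit, y33) - ref
    } else {
      warning("fitted decay does not reach 33% of peak: decay time NA",
              call. = FALSE)
    }
  }
  auc <- auc_trapezoid(w, onset, onset + auc_window, baseline)
  structure(list(peak_mV = peak, rise_time_ms = rise_time,
                 decay_time_ms = decay_time, auc_mVms = auc,
                 onset_ms = onset, condition = wf_attr(w, "condition")),
            class = "fepsp_params")
}

#' @export
print.fepsp_params <- function(x, ...) {
  cat(sprintf(
    "<fepsp_params:%s> peak %.3f mV, rise %.3f ms, decay %s ms, AUC %.3f mV*ms\n",
    x$condition %||% "?", x$peak_mV, x$rise_time_ms,
    ifelse(is.na(x$decay_time_ms), "NA", sprintf("%.3f", x$decay_time_ms)),
    x$auc_mVms))
  invisible(x)
}

#' Full fEPSP parameterization of one trace
#'
#' Onset detection, split at the extremum, independent Boltzmann fits of
#' rise and decay, and parameter extraction.
#'
#' @param w a [waveform()].
#' @inheritParams detect_onset
#' @inheritParams compute_params
#' @return An `fepsp_params` object (with `fits` attribute).
#' @export
analyze_fepsp <- function(w, baseline_window = NULL, multiplier = 3,
                          dwell_ms = 0.5, blank_ms = 1, auc_window = 30,
                          rise_fraction = 0.67) {
  onset <- detect_onset(w, baseline_window, multiplier, dwell_ms, blank_ms)
  stim <- wf_attr(w, "stimulus_ms")
  bw <- baseline_window %||% c(w$time_ms[1], stim)
  baseline <- mean(w$voltage_mV[w$time_ms >= bw[1] & w$time_ms < bw[2]])
  parts <- split_at_extremum(w, onset)
  rise_fit <- fit_boltzmann(parts$rise, "rise")
  decay_fit <- if (is.null(parts$decay)) NULL else
    tryCatch(fit_boltzmann(parts$decay, "decay"),
             neuroarbor_error = function(e) NULL)
  out <- compute_params(rise_fit, decay_fit, w, onset,
                        extremum_ms = parts$extremum_ms,
                        baseline = baseline, auc_window = auc_window,
                        rise_fraction = rise_fraction)
  attr(out, "fits") <- list(rise = rise_fit, decay = decay_fit)
  out
}

#' Percentage blockade of a response by a drug
#'
#' `(1 - auc_drug / auc_reference) * 100`, computed per slice; use
#' [blockade_summary()] to aggregate slices as mean +/- SEM.
#'
#' @param auc_drug,auc_reference AUC values (mV*ms), reference > 0.
#' @export
blockade_percent <- function(auc_drug, auc_reference) {
  if (any(auc_reference <= 0)) {
    stopf("degenerate_input", "reference AUC must be > 0")
  }
  (1 - auc_drug / auc_reference) * 100
}

#' Per-slice blockade percentages aggregated as mean +/- SEM
#'
#' @param df data.frame with columns `slice`, `condition`, `auc`.
#' @param reference reference condition (default `"aCSF"`).
#' @return data.frame: condition, n, mean_blockade_pct, sem_blockade_pct.
#' @export
blockade_summary <- function(df, reference = "aCSF") {
  conds <- setdiff(unique(df$condition), reference)
  out <- lapply(conds, function(cc) {
    slices <- intersect(df$slice[df$condition == cc],
                        df$slice[df$condition == reference])
    pct <- vapply(slices, function(s) {
      blockade_percent(df$auc[df$slice == s & df$condition == cc][1],
                       df$auc[df$slice == s & df$condition == reference][1])
    }, 0)
    data.frame(condition = cc, n = length(pct), mean_blockade_pct = mean(pct),
               sem_blockade_pct = sd(pct) / sqrt(length(pct)))
  })
  do.call(rbind, out)
}
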