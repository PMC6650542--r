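#' fEPSP waveform container
#'
#' A uniformly sampled extracellular voltage trace with its acquisition
#' metadata. fEPSPs are negative-going; voltages are signed mV.
#'
#' @param time_ms,voltage_mV numeric vectors of equal length; `time_ms`
#'   must be uniformly sampled (to 1e-9 ms).
#' @param stimulus_ms stimulus time within the trace.
#' @param condition pharmacological condition.
#' @param slice_id,animal_id identifiers.
#' @return A data.frame of class `fepsp_waveform` with columns `time_ms`,
#'   `voltage_mV` and metadata attributes.
#' @export
waveform <- function(time_ms, voltage_mV, stimulus_ms,
                     condition = c("aCSF", "CNQX", "CNQX+ifenprodil"),
                     slice_id = NA_character_, animal_id = NA_character_) {
  condition <- match.arg(condition)
  if (length(time_ms) != length(voltage_mV) || length(time_ms) < 2) {
    stopf("parameter_error", "time and voltage must match (length >= 2)")
  }
  dt <- diff(time_ms)
  if (max(abs(dt - dt[1])) > 1e-9) {
    stopf("parameter_error", "time axis must be uniformly sampled")
  }
  if (stimulus_ms < time_ms[1] || stimulus_ms > time_ms[length(time_ms)]) {
    stopf("parameter_error", "stimulus time outside the trace")
  }
  structure(data.frame(time_ms = time_ms, voltage_mV = voltage_mV),
            stimulus_ms = stimulus_ms, condition = condition,
            slice_id = slice_id, animal_id = animal_id,
            class = c("fepsp_waveform", "data.frame"))
}

wf_attr <- function(w, what) attr(w, what, exact = TRUE)

#' Parameters of the three-component fEPSP simulator
#'
#' Each receptor component is a difference-of-exponentials kinetic template
#' `(1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`, peak-normalized and scaled
#' to its (negative) amplitude. The pharmacological condition removes
#' components: `CNQX` blocks AMPA; `CNQX+ifenprodil` blocks AMPA and
#' GluN2B, leaving the GluN2A component. Defaults give GluN2A faster rise
#' and decay kinetics than GluN2B.
#'
#' @param amplitude_mV named vector (AMPA, GluN2B, GluN2A), all <= 0.
#' @param tau_rise_ms,tau_decay_ms named vectors, `tau_decay > tau_rise > 0`
#'   per component.
#' @param onset_latency_ms synaptic latency after the stimulus.
#' @param condition pharmacological condition of the simulated recording.
#' @param sampling_khz sampling rate.
#' @param duration_ms trace duration; must cover onset + 30 ms.
#' @param stimulus_ms stimulus time.
#' @param noise_sd_mV baseline Gaussian noise sd.
#' @param slice_id,animal_id identifiers carried into the waveform.
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @export
fepsp_sim_params <- function(
    amplitude_mV = c(AMPA = -0.45, GluN2B = -0.15, GluN2A = -0.25),
    tau_rise_ms = c(AMPA = 0.5, GluN2B = 7, GluN2A = 3),
    tau_decay_ms = c(AMPA = 8, GluN2B = 250, GluN2A = 50),
    onset_latency_ms = 2,
    condition = c("aCSF", "CNQX", "CNQX+ifenprodil"),
    sampling_khz = 10, duration_ms = 80, stimulus_ms = 5,
    noise_sd_mV = 0.01, slice_id = NA_character_,
    animal_id = NA_character_, rng_seed = NULL) {
  condition <- match.arg(condition)
  comp <- c("AMPA", "GluN2B", "GluN2A")
  for (nm in comp) {
    if (!(nm %in% names(amplitude_mV) && nm %in% names(tau_rise_ms) &&
          nm %in% names(tau_decay_ms))) {
      stopf("parameter_error", "component `%s` missing from parameters", nm)
    }
    if (tau_rise_ms[[nm]] <= 0 || tau_decay_ms[[nm]] <= tau_rise_ms[[nm]]) {
      stopf("parameter_error",
            "component `%s` needs tau_decay > tau_rise > 0", nm)
    }
    if (amplitude_mV[[nm]] > 0) {
      stopf("parameter_error",
            "component `%s` amplitude must be <= 0 (negative-going)", nm)
    }
  }
  if (duration_ms < stimulus_ms + onset_latency_ms + 30) {
    stopf("parameter_error", "duration must cover onset + 30 ms")
  }
  check_number(sampling_khz, "sampling_khz", lower = 0, strict_lower = TRUE)
  check_number(noise_sd_mV, "noise_sd_mV", lower = 0)
  structure(list(amplitude_mV = amplitude_mV[comp],
                 tau_rise_ms = tau_rise_ms[comp],
                 tau_decay_ms = tau_decay_ms[comp],
                 onset_latency_ms = onset_latency_ms, condition = condition,
                 sampling_khz = sampling_khz, duration_ms = duration_ms,
                 stimulus_ms = stimulus_ms, noise_sd_mV = noise_sd_mV,
                 slice_id = slice_id, animal_id = animal_id,
                 rng_seed = rng_seed),
            class = "fepsp_sim_params")
}

# peak-normalized difference-of-exponentials template, zero before onset
doe_template <- function(t, tau_r, tau_d) {
  tp <- fepsp_component_peak_time(tau_r, tau_d)
  fp <- (1 - exp(-tp / tau_r)) * exp(-tp / tau_d)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (1 - exp(-t[pos] / tau_r)) * exp(-t[pos] / tau_d) / fp
  out
}

#' Closed-form peak time of the difference-of-exponentials template (ms)
#' @param tau_rise_ms,tau_decay_ms component time constants (ms).
#' @export
fepsp_component_peak_time <- function(tau_rise_ms, tau_decay_ms) {
  tau_rise_ms * log((tau_rise_ms + tau_decay_ms) / tau_rise_ms)
}

#' Closed-form area of a peak-normalized component over a window
#'
#' Integral of the peak-normalized difference-of-exponentials from component
#' onset to `window_ms`, in ms (multiply by |amplitude| for mV*ms).
#'
#' @param tau_rise_ms,tau_decay_ms component time constants (ms).
#' @param window_ms integration window from component onset.
#' @export
fepsp_component_auc <- function(tau_rise_ms, tau_decay_ms, window_ms = 30) {
  tau_c <- tau_rise_ms * tau_decay_ms / (tau_rise_ms + tau_decay_ms)
  raw <- tau_decay_ms * (1 - exp(-window_ms / tau_decay_ms)) -
    tau_c * (1 - exp(-window_ms / tau_c))
  tp <- fepsp_component_peak_time(tau_rise_ms, tau_decay_ms)
  fp <- (1 - exp(-tp / tau_rise_ms)) * exp(-tp / tau_decay_ms)
  raw / fp
}

active_components <- function(condition) {
  switch(condition,
         "aCSF" = c("AMPA", "GluN2B", "GluN2A"),
         "CNQX" = c("GluN2B", "GluN2A"),
         "CNQX+ifenprodil" = "GluN2A")
}

#' Simulate an fEPSP waveform
#'
#' @param params a [fepsp_sim_params()] object.
#' @param components optional character vector overriding the condition's
#'   active components (used to isolate single components in tests).
#' @return A [waveform()].
#' @export
simulate_fepsp <- function(params, components = NULL) {
  if (!inherits(params, "fepsp_sim_params")) {
    stopf("parameter_error", "`params` must come from fepsp_sim_params()")
  }
  dt <- 1 / params$sampling_khz
  t <- seq(0, params$duration_ms, by = dt)
  onset <- params$stimulus_ms + params$onset_latency_ms
  act <- if (is.null(components)) active_components(params$condition) else
    components
  v <- numeric(length(t))
  for (nm in act) {
    v <- v + params$amplitude_mV[[nm]] *
      doe_template(t - onset, params$tau_rise_ms[[nm]],
                   params$tau_decay_ms[[nm]])
  }
  with_seed(params$rng_seed, {
    if (params$noise_sd_mV > 0) {
      v <- v + stats::rnorm(length(v), 0, params$noise_sd_mV)
    }
  })
  waveform(t, v, stimulus_ms = params$stimulus_ms,
           condition = params$condition, slice_id = params$slice_id,
           animal_id = params$animal_id)
}

#' Write / read a waveform as 2-column CSV with a JSON metadata sidecar
#' @param w a [waveform()].
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @export
write_waveform <- function(w, path) {
  write.csv(data.frame(time_ms = w$time_ms, voltage_mV = w$voltage_mV),
            path, row.names = FALSE)
  meta <- list(stimulus_ms = wf_attr(w, "stimulus_ms"),
               condition = wf_attr(w, "condition"),
               slice_id = wf_attr(w, "slice_id"),
               animal_id = wf_attr(w, "animal_id"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  waveform(df$time_ms, df$voltage_mV, stimulus_ms = meta$stimulus_ms,
           condition = meta$condition,
           slice_id = meta$slice_id %||% NA_character_,
           animal_id = meta$animal_id %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
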