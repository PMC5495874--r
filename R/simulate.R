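## topography (channels) of a dipole through a leadfield set: the source is
## snapped to the nearest source-space position; errors if the position is
## farther than 2 spacings from the space (outside its hull for practical
## purposes)
lf_topography <- function(lf, dipole) {
  pos <- lf$source_space$positions
  d2 <- rowSums(sweep(pos, 2, dipole$position)^2)
  j <- which.min(d2)
  if (sqrt(d2[j]) > 2 * lf$source_space$spacing)
    stopf("source at (%s) mm is outside the source space (nearest position %.1f mm away)",
          paste(format(dipole$position), collapse = ", "), sqrt(d2[j]))
  list(b = as.vector(lf$L[, lf_cols(j)] %*% dipole$moment), node = j)
}

#' Biphasic interictal-spike waveform template
#'
#' Double-Gaussian spike morphology: a main lobe of unit amplitude at time
#' zero and a rebound lobe of opposite sign. With the defaults
#' (`sigma = 9` ms, rebound at +16 ms with relative amplitude 0.4) the
#' template has roughly 70 ms of support.
#'
#' @param t times in ms.
#' @param sigma lobe width (Gaussian sd) in ms.
#' @param rebound_delay rebound-lobe latency in ms.
#' @param rebound_amp relative rebound amplitude.
#' @return template values (unit peak).
#' @export
spike_template <- function(t, sigma = 9, rebound_delay = 16, rebound_amp = 0.4) {
  g <- function(u) exp(-u^2 / (2 * sigma^2)) -
    rebound_amp * exp(-(u - rebound_delay)^2 / (2 * sigma^2))
  ## centre on the true maximum (the rebound lobe shifts it off u = 0) and
  ## normalize to unit peak
  tm <- stats::optimize(g, c(-2 * sigma, sigma), maximum = TRUE)$maximum
  g(t + tm) / g(tm)
}

## unimodal somatosensory-evoked waveform: Gaussian peaking at `latency` ms
sep_waveform <- function(t, latency = 20, sigma = 4) {
  exp(-(t - latency)^2 / (2 * sigma^2))
}

raw_trials <- function(data, channel_meta, sampling_rate, event_latency) {
  stopifnot(dim(data)[1] == nrow(channel_meta))
  structure(list(data = data, channel_meta = channel_meta,
                 sampling_rate = sampling_rate, event_latency = event_latency),
            class = "raw_trials")
}

## per-modality noise std for a requested peak-amplitude SNR
modality_noise_std <- function(clean, modality, snr_eeg, snr_meg) {
  std <- numeric(length(modality))
  for (mod in unique(modality)) {
    sel <- modality == mod
    pk <- max(abs(clean[sel, , drop = FALSE]))
    snr <- if (mod == "eeg") snr_eeg else snr_meg
    std[sel] <- pk / snr
  }
  std
}

#' Simulate somatosensory-evoked trials
#'
#' Each trial is the leadfield topography of a fixed tangential source
#' scaled by a unimodal waveform peaking at 20 ms, plus i.i.d. Gaussian
#' noise per channel. The noise standard deviation per modality is set so
#' the single-trial peak-amplitude SNR matches the request; averaging n
#' trials therefore raises the SNR by sqrt(n).
#'
#' @param leadfields a `leadfield_set` (EEG, MEG or combined).
#' @param source a [dipole_source()] on (or near) the source space.
#' @param snr_eeg,snr_meg single-trial peak-amplitude SNR per modality
#'   (noise-free for `Inf`).
#' @param n_trials number of trials.
#' @param seed RNG seed (local; the global RNG state is untouched).
#' @param sampling_rate Hz.
#' @param duration trial length in ms.
#' @return A `raw_trials` object (`data` channels x time x trials).
#' @export
simulate_sep_recordings <- function(leadfields, source, snr_eeg = 3, snr_meg = 3,
                                    n_trials = 100, seed = 1,
                                    sampling_rate = 1000, duration = 60) {
  stopifnot(inherits(leadfields, "leadfield_set"), n_trials >= 1,
            snr_eeg > 0, snr_meg > 0)
  tp <- lf_topography(leadfields, source)
  nt <- round(duration * sampling_rate / 1000) + 1
  tms <- (seq_len(nt) - 1) / sampling_rate * 1000
  w <- sep_waveform(tms)
  clean <- tp$b %o% w
  std <- modality_noise_std(clean, leadfields$modality, snr_eeg, snr_meg)
  nc <- nrow(clean)
  data <- with_seed(seed, {
    out <- array(0, dim = c(nc, nt, n_trials))
    for (tr in seq_len(n_trials))
      out[, , tr] <- clean + matrix(rnorm(nc * nt, sd = std), nc, nt)
    out
  })
  meta <- data.frame(name = leadfields$channel_names,
                     modality = leadfields$modality,
                     noise_std = std, stringsAsFactors = FALSE)
  raw_trials(data, meta, sampling_rate,
             event_latency = rep(which.max(w), n_trials))
}

#' Interictal-discharge simulation configuration
#'
#' Two dipolar foci with a propagation delay: the onset source activates
#' `delay` ms before the peak source (default 23 ms); both share the
#' biphasic [spike_template()]. Defaults encode the study conditions used
#' throughout the package: 10 trials at single-trial peak-amplitude SNR 5
#' per modality.
#'
#' @param onset_source,peak_source [dipole_source()] objects (moments nA.m).
#' @param delay propagation delay in ms (>= 0).
#' @param n_trials number of discharges.
#' @param snr_eeg,snr_meg single-trial peak-amplitude SNR per modality;
#'   averaging the trials raises the SNR by `sqrt(n_trials)`.
#' @param sampling_rate Hz.
#' @param duration trial length ms; the nominal spike peak sits at
#'   `peak_latency` ms from trial onset.
#' @param peak_latency ms from trial start to the spike peak.
#' @param template_args list passed to [spike_template()].
#' @param seed RNG seed.
#' @return A `spike_sim_config`.
#' @export
spike_sim_config <- function(onset_source, peak_source, delay = 23,
                             n_trials = 10, snr_eeg = 5, snr_meg = 5,
                             sampling_rate = 1000, duration = 400,
                             peak_latency = 250, template_args = list(),
                             seed = 1) {
  stopifnot(inherits(onset_source, "dipole_source"),
            inherits(peak_source, "dipole_source"),
            delay >= 0, n_trials >= 1, snr_eeg > 0, snr_meg > 0)
  structure(list(onset_source = onset_source, peak_source = peak_source,
                 delay = delay, n_trials = n_trials,
                 snr_eeg = snr_eeg, snr_meg = snr_meg,
                 sampling_rate = sampling_rate, duration = duration,
                 peak_latency = peak_latency, template_args = template_args,
                 seed = seed),
            class = "spike_sim_config")
}

#' Simulate interictal epileptic discharges from two propagating foci
#'
#' The onset focus fires the spike template `delay` ms before the peak
#' focus; `event_latency` marks the peak focus maximum. Per-modality white
#' noise is added per channel as in [simulate_sep_recordings()] (the SNR is
#' the single-trial peak-amplitude SNR).
#'
#' @param leadfields a `leadfield_set`.
#' @param config a [spike_sim_config()].
#' @return A `raw_trials` object.
#' @export
simulate_ied_recordings <- function(leadfields, config) {
  stopifnot(inherits(leadfields, "leadfield_set"),
            inherits(config, "spike_sim_config"))
  sr <- config$sampling_rate
  dsamp <- config$delay * sr / 1000
  if (abs(dsamp - round(dsamp)) > 1e-9) {
    near <- round(dsamp) * 1000 / sr
    stopf("delay %g ms is not a whole number of samples at %g Hz; nearest representable is %g ms",
          config$delay, sr, near)
  }
  tp_on <- lf_topography(leadfields, config$onset_source)
  tp_pk <- lf_topography(leadfields, config$peak_source)
  nt <- round(config$duration * sr / 1000) + 1
  tms <- (seq_len(nt) - 1) / sr * 1000 - config$peak_latency # 0 at spike peak
  w_pk <- do.call(spike_template, c(list(t = tms), config$template_args))
  w_on <- do.call(spike_template, c(list(t = tms + config$delay), config$template_args))
  clean <- tp_pk$b %o% w_pk + tp_on$b %o% w_on
  std <- modality_noise_std(clean, leadfields$modality, config$snr_eeg, config$snr_meg)
  nc <- nrow(clean)
  data <- with_seed(config$seed, {
    out <- array(0, dim = c(nc, nt, config$n_trials))
    for (tr in seq_len(config$n_trials))
      out[, , tr] <- clean + matrix(rnorm(nc * nt, sd = std), nc, nt)
    out
  })
  meta <- data.frame(name = leadfields$channel_names,
                     modality = leadfields$modality,
                     noise_std = std, stringsAsFactors = FALSE)
  raw_trials(data, meta, sr,
             event_latency = rep(which.min(abs(tms)), config$n_trials))
}

#' @export
print.raw_trials <- function(x, ...) {
  d <- dim(x$data)
  cat("Raw trials:", d[1], "channels x", d[2], "samples x", d[3], "trials @",
      x$sampling_rate, "Hz\n")
  invisible(x)
}
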