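#' Configuration for the synthetic ECG generator
#'
#' Each heartbeat is modeled as a sum of five Gaussian kernels (P, Q, R, S, T),
#' one set per beat, scaled per lead, with additive white Gaussian noise and
#' quantization to a configurable ADC grid. Ground-truth wave borders are
#' defined by construction as kernel center +/- 3 widths (clipped so that
#' consecutive waves never overlap), which makes the generator usable as a
#' delineation and codec oracle.
#'
#' Default morphology (amplitudes in microvolts, times in seconds relative to
#' the R center): P(120, -0.16, 0.020), Q(-100, -0.024, 0.007),
#' R(1000, 0, 0.010), S(-180, 0.026, 0.008), T(320, 0.25, 0.040). These give
#' a ~95 ms QRS, ~175 ms P-onset-to-QRS-onset interval and a T-end 0.37 s
#' after the R center, so beats remain disjoint up to ~100 bpm.
#'
#' @param heart_rate_bpm heart rate, beats per minute.
#' @param duration_s record duration, seconds.
#' @param fs sampling rate, Hz.
#' @param n_leads number of leads.
#' @param lead_gains per-lead multiplicative gains; defaults to a fixed
#'   12-lead-like profile recycled to `n_leads`.
#' @param wave_params 5 x 3 numeric matrix with rows P, Q, R, S, T and columns
#'   `amp_uv`, `center_s`, `width_s`.
#' @param noise_rms_uv white-noise RMS amplitude per lead, microvolts.
#' @param bits ADC bit depth; amplitudes are quantized to
#'   `2 * full_scale_uv / 2^bits` microvolts per LSB. Use `Inf` to disable
#'   quantization (exact real-valued amplitudes).
#' @param full_scale_uv ADC full scale (+/-), microvolts. The default 12 bits
#'   over +/-5 mV gives ~2.44 uV per LSB.
#' @param seed integer seed; identical configurations produce bit-identical
#'   records.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(heart_rate_bpm = 60, duration_s = 10, fs = 500,
                         n_leads = 12, lead_gains = NULL,
                         wave_params = default_wave_params(),
                         noise_rms_uv = 5, bits = 12, full_scale_uv = 5000,
                         seed = 1L) {
  if (heart_rate_bpm <= 0 || duration_s <= 0 || fs <= 0)
    stop("heart_rate_bpm, duration_s and fs must all be positive", call. = FALSE)
  if (n_leads < 1) stop("n_leads must be >= 1", call. = FALSE)
  if (noise_rms_uv < 0) stop("noise_rms_uv must be >= 0", call. = FALSE)
  wave_params <- as.matrix(wave_params)
  if (!all(dim(wave_params) == c(5, 3)))
    stop("wave_params must be a 5 x 3 matrix (P,Q,R,S,T x amp,center,width)",
         call. = FALSE)
  rownames(wave_params) <- c("P", "Q", "R", "S", "T")
  colnames(wave_params) <- c("amp_uv", "center_s", "width_s")
  if (any(wave_params[, "width_s"] <= 0))
    stop("wave widths must be positive", call. = FALSE)
  if (is.unsorted(wave_params[, "center_s"], strictly = TRUE))
    stop("wave centers must be strictly ordered P < Q < R < S < T", call. = FALSE)
  if (is.null(lead_gains)) lead_gains <- default_lead_gains(n_leads)
  lead_gains <- rep_len(as.numeric(lead_gains), n_leads)
  structure(
    list(heart_rate_bpm = heart_rate_bpm, duration_s = duration_s, fs = fs,
         n_leads = as.integer(n_leads), lead_gains = lead_gains,
         wave_params = wave_params, noise_rms_uv = noise_rms_uv,
         bits = as.numeric(bits), full_scale_uv = full_scale_uv,
         seed = as.integer(seed)),
    class = "synth_config")
}

#' @rdname synth_config
#' @export
default_wave_params <- function() {
  m <- rbind(P = c(120, -0.160, 0.020),
             Q = c(-100, -0.024, 0.007),
             R = c(1000, 0.000, 0.010),
             S = c(-180, 0.026, 0.008),
             T = c(320, 0.250, 0.040))
  colnames(m) <- c("amp_uv", "center_s", "width_s")
  m
}

default_lead_gains <- function(n_leads) {
  base <- c(0.70, 1.00, 0.45, -0.85, 0.30, 0.75,
            -0.50, 0.60, 0.90, 1.10, 1.00, 0.85)
  rep_len(base, n_leads)
}

#' Generate a synthetic annotated multi-lead ECG
#'
#' Beats are placed at R centers `(i - 1/2) * RR` for `i = 1..round(rate *
#' duration / 60)`. Per-beat ground-truth borders are P-onset, P-end
#' (P center -/+ 3 widths), QRS-onset (Q center - 3 widths), QRS-end
#' (S center + 3 widths) and T-end (T center + 3 widths), expressed as 0-based
#' fractional sample positions; adjacent borders are clipped so they never
#' overlap within or across beats.
#'
#' @param config a [synth_config].
#' @return A list with elements `ecg` (a [uniform_ecg]) and `annotations`
#'   (a `beat_annotations` data frame, see [beat_annotations]).
#' @examples
#' rec <- generate_ecg(synth_config(duration_s = 4, n_leads = 2, seed = 7))
#' rec$ecg
#' rec$annotations
#' @export
generate_ecg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  rr <- 60 / config$heart_rate_bpm
  n_beats <- round(config$duration_s / rr)
  r_centers <- (seq_len(n_beats) - 0.5) * rr

  wp <- config$wave_params
  clean <- numeric(n)
  for (w in seq_len(5)) {
    for (rc in r_centers) {
      mu <- rc + wp[w, "center_s"]
      sd <- wp[w, "width_s"]
      # Gaussian support is effectively +/- 5 sd; restrict for speed
      lo <- max(1L, floor((mu - 5 * sd) * fs) + 1L)
      hi <- min(n, ceiling((mu + 5 * sd) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      clean[idx] <- clean[idx] +
        wp[w, "amp_uv"] * exp(-0.5 * ((t[idx] - mu) / sd)^2)
    }
  }

  lsb <- if (is.finite(config$bits))
    2 * config$full_scale_uv / 2^config$bits else NA_real_
  sig <- matrix(0, n, config$n_leads)
  old_seed <- set_local_seed(config$seed)
  on.exit(restore_seed(old_seed))
  for (l in seq_len(config$n_leads)) {
    x <- clean * config$lead_gains[l]
    if (config$noise_rms_uv > 0)
      x <- x + stats::rnorm(n, sd = config$noise_rms_uv)
    sig[, l] <- if (is.finite(lsb)) round(x / lsb) * lsb else x
  }

  ann <- annotate_beats(r_centers, wp, fs, n)
  list(ecg = uniform_ecg(sig, fs = fs,
                         lead_labels = if (config$n_leads == 12) std_12_leads()
                                       else paste0("L", seq_len(config$n_leads)),
                         resolution_uv = lsb),
       annotations = ann)
}

annotate_beats <- function(r_centers, wp, fs, n) {
  b <- lapply(seq_along(r_centers), function(i) {
    rc <- r_centers[i]
    c(p_on = rc + wp["P", "center_s"] - 3 * wp["P", "width_s"],
      p_end = rc + wp["P", "center_s"] + 3 * wp["P", "width_s"],
      qrs_on = rc + wp["Q", "center_s"] - 3 * wp["Q", "width_s"],
      qrs_end = rc + wp["S", "center_s"] + 3 * wp["S", "width_s"],
      t_end = rc + wp["T", "center_s"] + 3 * wp["T", "width_s"]) * fs
  })
  m <- do.call(rbind, b)
  # clip to strict ordering within beats and non-overlap across beats,
  # and to the signal support
  eps <- 1e-6
  flat <- as.numeric(t(m))
  flat <- pmin(pmax(flat, 0), n - 1)
  flat <- cummax_strict(flat, eps)
  m <- matrix(flat, ncol = 5, byrow = TRUE)
  colnames(m) <- c("p_on", "p_end", "qrs_on", "qrs_end", "t_end")
  beat_annotations(m)
}

cummax_strict <- function(x, eps) {
  for (i in seq_along(x)[-1]) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
  x
}

# Seed handling: run under a local RNG state so generation is reproducible
# without clobbering the caller's stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Generate a bandlimited multitone test signal
#'
#' Sum of unit-amplitude sines at the given frequencies, single lead, used as
#' an analytic oracle input for reconstruction tests. A frequency of 0 yields
#' a DC component of amplitude 1.
#'
#' @param f_components frequencies in Hz, all strictly below `fs / 2`.
#' @param fs sampling rate, Hz.
#' @param duration_s duration, seconds.
#' @return A single-lead [uniform_ecg] with `resolution_uv = NA` (exact
#'   amplitudes, no ADC quantization).
#' @export
generate_bandlimited <- function(f_components, fs, duration_s) {
  if (any(f_components >= fs / 2))
    stop("all frequency components must be below fs/2 (aliasing)", call. = FALSE)
  if (any(f_components < 0)) stop("frequencies must be >= 0", call. = FALSE)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (f in f_components)
    x <- x + if (f == 0) rep(1, n) else sin(2 * pi * f * t)
  uniform_ecg(x, fs = fs, lead_labels = "tone", resolution_uv = NA_real_)
}
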