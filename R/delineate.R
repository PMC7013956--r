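#' Detect heartbeats (QRS complexes) in a multi-lead ECG
#'
#' Pan-Tompkins-style detector: each lead is band-pass filtered to the QRS
#' band (5-25 Hz, zero-phase Butterworth), differentiated and squared; the
#' cross-lead energy sum is smoothed with a 150 ms moving average and peaks
#' above an adaptive threshold (30% of the envelope maximum) are taken as
#' beats, with a 200 ms refractory period. Because the threshold is relative,
#' detections are invariant to a global amplitude rescaling.
#'
#' @param ecg a [uniform_ecg] with at least 2 s of signal.
#' @param refractory_s minimum spacing between detections, seconds.
#' @return Numeric vector of QRS fiducial positions (0-based sample
#'   positions), strictly increasing; empty for a flat signal.
#' @export
detect_beats <- function(ecg, refractory_s = 0.2) {
  stopifnot(inherits(ecg, "uniform_ecg"))
  fs <- ecg$fs
  n <- n_samples(ecg)
  if ((n - 1) / fs < 2)
    stop("detect_beats needs at least 2 s of signal", call. = FALSE)

  bp <- qrs_bandpass(ecg$signal, fs)
  d <- apply(bp, 2, function(x) c(0, diff(x)))
  energy <- rowSums(d^2)
  env <- moving_average(energy, max(3L, round(0.150 * fs)))
  peak <- max(env)
  if (peak <= 0) return(numeric(0))
  thr <- 0.3 * peak

  above <- env > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- numeric(0)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    cand <- c(cand, seg[which.max(env[seg])])
  }
  # refractory: keep the larger of any pair closer than refractory_s
  cand <- sort(cand)
  keep <- rep(TRUE, length(cand))
  i <- 1
  while (i < length(cand)) {
    j <- i + 1
    while (j <= length(cand) && keep[j] == FALSE) j <- j + 1
    if (j > length(cand)) break
    if ((cand[j] - cand[i]) / fs < refractory_s) {
      if (env[cand[j]] > env[cand[i]]) { keep[i] <- FALSE; i <- j }
      else keep[j] <- FALSE
    } else i <- j
  }
  cand <- cand[keep]

  # refine to the cross-lead RMS peak of the band-passed signal
  half <- round(0.06 * fs)
  rms_bp <- sqrt(rowMeans(bp^2))
  refined <- vapply(cand, function(p) {
    lo <- max(1, p - half); hi <- min(n, p + half)
    (lo:hi)[which.max(rms_bp[lo:hi])]
  }, 0)
  sort(unique(refined)) - 1  # 0-based
}

qrs_bandpass <- function(sig, fs) {
  ny <- fs / 2
  bf <- signal::butter(3, c(5, min(25, 0.9 * ny)) / ny, type = "pass")
  apply(sig, 2, function(x) as.numeric(signal::filtfilt(bf, x)))
}

moving_average <- function(x, w) {
  if (w %% 2 == 0) w <- w + 1L
  k <- rep(1 / w, w)
  y <- as.numeric(stats::filter(x, k, sides = 2, circular = FALSE))
  # fill edge NAs with nearest computed value
  nas <- is.na(y)
  if (any(nas)) {
    first <- which(!nas)[1]
    last <- max(which(!nas))
    y[seq_len(first - 1)] <- y[first]
    if (last < length(y)) y[(last + 1):length(y)] <- y[last]
  }
  y
}

#' Delineate ECG wave borders
#'
#' Finds the five wave borders (P-onset, P-end, QRS-onset, QRS-end, T-end) of
#' every detected beat. Borders are determined jointly for all leads on the
#' cross-lead root-mean-square combination of the signal. The criterion is
#' derivative-energy based: starting at the wave peak and moving outward, a
#' border is placed where the smoothed derivative energy of the combined
#' signal falls below `k` times the local noise RMS (default `k = 2`), i.e.
#' where the wave energy sinks into the background noise.
#'
#' Beats whose P or T wave cannot be resolved (amplitude below the noise
#' floor, or insufficient room at the record edges) are flagged; their
#' unresolved borders are filled with nominal offsets so the annotation
#' remains well-ordered, and downstream coding treats flagged spans at
#' maximum relevance.
#'
#' @param ecg a [uniform_ecg].
#' @param beats QRS fiducial positions from [detect_beats] (0-based samples),
#'   or externally supplied equivalents.
#' @param k noise-multiple threshold for the border criterion.
#' @return A [beat_annotations] data frame, one row per beat.
#' @export
delineate <- function(ecg, beats, k = 2) {
  stopifnot(inherits(ecg, "uniform_ecg"))
  fs <- ecg$fs
  n <- n_samples(ecg)
  if (length(beats) == 0)
    return(beat_annotations(matrix(numeric(0), 0, 5)))
  beats <- sort(as.numeric(beats)) + 1  # to 1-based indices

  s <- sqrt(rowMeans(ecg$signal^2))
  d <- c(0, diff(s)) * fs  # derivative, uV/s
  e_qrs <- sqrt(pmax(moving_average(d^2, round(0.012 * fs)), 0))
  # P and T flanks are slow: differentiate a pre-smoothed signal so the
  # derivative-energy noise floor does not swamp the gentle wave tails
  s_lp <- moving_average(s, round(0.016 * fs))
  d_lp <- c(0, diff(s_lp)) * fs
  e_pt <- sqrt(pmax(moving_average(d_lp^2, round(0.024 * fs)), 0))
  s_smooth <- moving_average(s, round(0.024 * fs))

  # background level of the derivative energy: the quiet (lower-quantile)
  # portion of the record, floored at 1% of the peak energy so the
  # emergence criterion stays defined for near-noiseless records
  noise_qrs <- max(stats::quantile(e_qrs, 0.25, names = FALSE),
                   0.01 * max(e_qrs), 1e-9)
  noise_pt <- max(stats::quantile(e_pt, 0.25, names = FALSE),
                  0.01 * max(e_pt), 1e-9)
  base_level <- stats::median(s_smooth)
  noise_amp <- pmax(stats::mad(s_smooth), 1e-9)

  nb <- length(beats)
  out <- matrix(NA_real_, nb, 5)
  flagged <- rep(FALSE, nb)
  rr_med <- if (nb > 1) stats::median(diff(beats)) else round(0.8 * fs)

  for (i in seq_len(nb)) {
    r <- round(beats[i])
    prev_lim <- if (i > 1) round(beats[i - 1] + 0.1 * fs) else 1
    next_lim <- if (i < nb) round(beats[i + 1] - 0.1 * fs) else n

    qrs_on <- search_outward(e_qrs, from = r, dir = -1,
                             thr = k * noise_qrs, fs = fs,
                             limit = max(prev_lim, r - round(0.12 * fs)))
    qrs_end <- search_outward(e_qrs, from = r, dir = +1,
                              thr = k * noise_qrs, fs = fs,
                              limit = min(next_lim, r + round(0.12 * fs)))

    # P wave: bump of the smoothed combined signal left of QRS onset
    p_lo <- max(prev_lim, qrs_on - round(0.30 * fs))
    p_hi <- qrs_on - round(0.02 * fs)
    p_on <- p_end <- NA_real_
    if (p_hi - p_lo > round(0.04 * fs)) {
      win <- p_lo:p_hi
      p_peak <- win[which.max(s_smooth[win])]
      if (s_smooth[p_peak] - base_level > 3 * noise_amp) {
        p_on <- search_outward(e_pt, from = p_peak, dir = -1,
                               thr = k * noise_pt, fs = fs, limit = p_lo)
        p_end <- search_outward(e_pt, from = p_peak, dir = +1,
                                thr = k * noise_pt, fs = fs, limit = p_hi)
      }
    }

    # T wave: bump right of QRS end
    t_lo <- qrs_end + round(0.06 * fs)
    t_hi <- min(next_lim, r + round(0.55 * rr_med), n)
    t_end <- NA_real_
    if (t_hi - t_lo > round(0.06 * fs)) {
      win <- t_lo:t_hi
      t_peak <- win[which.max(s_smooth[win])]
      if (s_smooth[t_peak] - base_level > 3 * noise_amp) {
        t_end <- search_outward(e_pt, from = t_peak, dir = +1,
                                thr = k * noise_pt, fs = fs, limit = t_hi)
      }
    }

    if (is.na(p_on) || is.na(p_end) || is.na(t_end)) flagged[i] <- TRUE
    # nominal fallbacks keep the annotation well-ordered
    if (is.na(p_on)) p_on <- qrs_on - round(0.20 * fs)
    if (is.na(p_end)) p_end <- qrs_on - round(0.06 * fs)
    if (is.na(t_end)) t_end <- min(qrs_end + round(0.35 * fs), t_hi)
    out[i, ] <- c(p_on, p_end, qrs_on, qrs_end, t_end)
  }

  out <- out - 1           # back to 0-based positions
  out[out < 0] <- 0
  out[out > n - 1] <- n - 1
  flat <- as.numeric(t(out))
  flat <- cummax_strict(flat, 1e-6)
  out <- matrix(flat, ncol = 5, byrow = TRUE)
  colnames(out) <- c("p_on", "p_end", "qrs_on", "qrs_end", "t_end")
  beat_annotations(out, flagged = flagged)
}

# Move outward from a wave peak until the smoothed derivative energy stays
# below `thr` for a sustained run (12 ms); returns the first sample of that
# run, or the search limit if the energy never settles.
search_outward <- function(e, from, dir, thr, fs, limit) {
  run_len <- max(2L, round(0.012 * fs))
  idx <- if (dir < 0) seq(from, max(limit, 1), by = -1)
         else seq(from, min(limit, length(e)), by = 1)
  below <- e[idx] < thr
  run <- 0L
  for (j in seq_along(idx)) {
    if (below[j]) {
      run <- run + 1L
      if (run >= run_len) return(idx[j - run_len + 1L])
    } else run <- 0L
  }
  idx[length(idx)]
}
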