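FEATURE_NAMES <- c("RR_int", "QRS_dur", "QT_int", "QTp_int", "P_dur",
                   "PR_int", "QRS_peaks_no", "Q_wave_exist",
                   "Delta_wave_exist", "T_shape", "P_shape", "ST_shape",
                   "QRSp_amp", "QRSn_amp", "P_amp", "T_amp",
                   "ST_elevation", "ST_slope")

WDD_WEIGHTS <- c(2.5, 2.5, 1, 1, 2, 2, 1, 0.5, 0.1, 1.5, 1, 3,
                 1.5, 1.5, 1, 1, 3, 3)

wdd_numeric_idx <- c(1:7, 13:18)
wdd_boolean_idx <- c(8, 9)
wdd_categorical_idx <- c(10, 11, 12)

# measurement floors entering the WDD normalization denominator: differences
# in a feature whose magnitude sits below its interpretive measurement
# tolerance (1 ms for durations, 1 peak, 25 uV for amplitudes per the
# interpretive-electrocardiograph accuracy limit, 500 uV/s for the ST slope
# threshold) must not register as full mismatches
WDD_FLOORS <- c(RR_int = 1, QRS_dur = 1, QT_int = 1, QTp_int = 1,
                P_dur = 1, PR_int = 1, QRS_peaks_no = 1,
                QRSp_amp = 25, QRSn_amp = 25, P_amp = 25, T_amp = 25,
                ST_elevation = 25, ST_slope = 500)

#' Extract the 18 diagnostic features of one heartbeat
#'
#' Computes the feature vector entering the weighted diagnostic distortion:
#' intervals from the wave borders (ms), amplitudes from regional extrema
#' relative to the PR-segment baseline (microvolts), the QRS peak count, Q-
#' and delta-wave flags, wave shape classes, and the ST measurements. Shape
#' conventions: T and P are `positive` / `negative` / `biphasic` by the
#' signed-area split of the wave (biphasic when the minority polarity holds
#' more than 25% of the absolute area); ST is `upsloping` / `horizontal` /
#' `downsloping` by the regression slope of the early ST segment against
#' thresholds of +/-0.5 uV/ms; ST elevation is read 60 ms after QRS-end;
#' QTp runs from QRS-onset to the T peak.
#'
#' @param ecg a [uniform_ecg].
#' @param annotation one row of a [beat_annotations] data frame (or a
#'   vector of the five borders in samples).
#' @param lead lead (column) to measure on.
#' @param rr_ms RR interval in ms, taken from the beat context (`NA` for an
#'   isolated beat; see [extract_features_all]).
#' @return A list of class `diagnostic_features` with the 18 named entries.
#' @export
extract_features <- function(ecg, annotation, lead = 1, rr_ms = NA_real_) {
  stopifnot(inherits(ecg, "uniform_ecg"))
  fs <- ecg$fs
  n <- n_samples(ecg)
  b <- if (is.data.frame(annotation))
    as.numeric(annotation[1, c("p_on", "p_end", "qrs_on", "qrs_end",
                               "t_end")])
  else as.numeric(annotation)[1:5]
  if (any(b < 0) || any(b > n - 1))
    stop("annotation lies outside the record", call. = FALSE)
  idx <- function(lo, hi) max(1, floor(lo) + 1):min(n, ceiling(hi) + 1)
  xlead <- ecg$signal[, lead]
  baseline <- stats::median(xlead[idx(b[2], b[3])])
  x <- xlead - baseline

  ms <- function(ds) ds / fs * 1000

  qrs_i <- idx(b[3], b[4])
  qrs_x <- x[qrs_i]
  r_amp <- max(abs(qrs_x))
  r_pos <- qrs_i[which.max(abs(qrs_x))]

  # alternating-sign extrema above 10% of the R amplitude
  ext <- local_extrema(qrs_x)
  ext <- ext[abs(qrs_x[ext]) >= 0.1 * r_amp]
  n_peaks <- count_alternating(sign(qrs_x[ext]))

  q_exist <- any(x[idx(b[3], (r_pos - 1))] <= -max(25, 0.05 * r_amp)) &&
    x[r_pos] > 0
  delta_exist <- has_delta_wave(x, b, fs, r_amp)

  t_i <- idx(b[4], b[5])
  t_x <- x[t_i]
  t_pos <- t_i[which.max(abs(t_x))]
  p_i <- idx(b[1], b[2])
  p_x <- x[p_i]
  p_pos <- p_i[which.max(abs(p_x))]

  # 20 ms window mean around QRS-end + 60 ms, as measured on averaged beats
  st_win <- idx(b[4] + 0.050 * fs, min(b[4] + 0.070 * fs, n - 1))
  st_elev <- if (length(st_win)) mean(x[st_win]) else NA_real_
  st_seg <- idx(b[4] + 0.02 * fs, min(b[4] + 0.10 * fs, b[5]))
  st_slope <- if (length(st_seg) >= 3)
    unname(stats::coef(stats::lm(x[st_seg] ~ I((st_seg - 1) / fs)))[2])
  else 0
  st_shape <- if (st_slope > 500) "upsloping"
              else if (st_slope < -500) "downsloping" else "horizontal"

  out <- list(
    RR_int = rr_ms,
    QRS_dur = ms(b[4] - b[3]),
    QT_int = ms(b[5] - b[3]),
    QTp_int = ms((t_pos - 1) - b[3]),
    P_dur = ms(b[2] - b[1]),
    PR_int = ms(b[3] - b[1]),
    QRS_peaks_no = n_peaks,
    Q_wave_exist = q_exist,
    Delta_wave_exist = delta_exist,
    T_shape = shape_class(t_x),
    P_shape = shape_class(p_x),
    ST_shape = st_shape,
    QRSp_amp = max(qrs_x),
    QRSn_amp = min(qrs_x),
    P_amp = x[p_pos],
    T_amp = x[t_pos],
    ST_elevation = st_elev,
    ST_slope = st_slope)
  class(out) <- "diagnostic_features"
  out
}

local_extrema <- function(x) {
  if (length(x) < 3) return(integer(0))
  d <- diff(x)
  which(d[-length(d)] * d[-1] < 0) + 1L
}

count_alternating <- function(signs) {
  signs <- signs[signs != 0]
  if (length(signs) == 0) return(0L)
  sum(c(TRUE, diff(signs) != 0))
}

shape_class <- function(w) {
  pos <- sum(pmax(w, 0))
  neg <- sum(pmax(-w, 0))
  tot <- pos + neg
  if (tot == 0) return("positive")
  if (min(pos, neg) / tot > 0.25) "biphasic"
  else if (pos >= neg) "positive" else "negative"
}

# delta wave: a slurred initial upstroke - early QRS samples that have
# already risen towards the dominant deflection (15-50% of its amplitude,
# same polarity) while the local slope is still well below the steepest QRS
# slope; opposite-polarity Q/S troughs are excluded
has_delta_wave <- function(x, b, fs, r_amp) {
  lo <- floor(b[3]) + 1
  hi <- min(floor(b[3] + 0.04 * fs) + 1, floor(b[4]) + 1)
  if (hi - lo < 2) return(FALSE)
  qrs <- (floor(b[3]) + 1):(floor(b[4]) + 1)
  max_slope <- max(abs(diff(x[qrs])))
  r_sign <- sign(x[qrs][which.max(abs(x[qrs]))])
  seg <- lo:(hi - 1)
  rise <- x[seg] * r_sign
  any(rise > 0.15 * r_amp & rise < 0.5 * r_amp &
        abs(diff(x[lo:hi])) < 0.15 * max_slope)
}

#' @rdname extract_features
#' @param annotations a full [beat_annotations] data frame; RR intervals are
#'   taken from consecutive QRS onsets (the first beat inherits the interval
#'   to its successor).
#' @return `extract_features_all` returns a list of `diagnostic_features`,
#'   one per beat.
#' @export
extract_features_all <- function(ecg, annotations, lead = 1) {
  stopifnot(is_beat_annotations(annotations))
  nb <- nrow(annotations)
  qon <- annotations$qrs_on
  rr <- if (nb > 1) diff(qon) / ecg$fs * 1000 else NA_real_
  rr_ms <- if (nb > 1) c(rr[1], rr) else NA_real_
  lapply(seq_len(nb), function(i)
    extract_features(ecg, annotations[i, ], lead = lead, rr_ms = rr_ms[i]))
}

#' Weighted diagnostic distortion (WDD)
#'
#' Weighted quadratic distance between two 18-feature heartbeat vectors:
#' `WDD = t(db) %*% L %*% db / tr(L) * 100` with the heuristic diagonal
#' weight matrix `L = diag(2.5, 2.5, 1, 1, 2, 2, 1, 0.5, 0.1, 1.5, 1, 3,
#' 1.5, 1.5, 1, 1, 3, 3)`. Each difference component is normalized to
#' `[0, 1]`: numeric features as `|b - bh| / max(|b|, |bh|, eps)` (clipped),
#' boolean and categorical features as 0/1 on mismatch; so the WDD is
#' symmetric and bounded by 100. The guard `eps` defaults to a per-feature
#' measurement floor (1 ms for intervals, 25 uV for amplitudes, 500 uV/s for
#' the ST slope), so features that are essentially zero on both sides - an
#' isoelectric ST segment, say - do not register noise as full distortion.
#'
#' @param beta,beta_hat `diagnostic_features` of the compared beats.
#' @param eps guard against zero denominators in the normalization: a single
#'   number, or `NULL` for the per-feature floors described above.
#' @return WDD in percent.
#' @export
wdd <- function(beta, beta_hat, eps = NULL) {
  if (!all(FEATURE_NAMES %in% names(beta)) ||
      !all(FEATURE_NAMES %in% names(beta_hat)))
    stop("both feature vectors must carry all 18 diagnostic features",
         call. = FALSE)
  db <- numeric(18)
  for (j in wdd_numeric_idx) {
    a <- as.numeric(beta[[FEATURE_NAMES[j]]])
    b <- as.numeric(beta_hat[[FEATURE_NAMES[j]]])
    if (is.na(a) && is.na(b)) { db[j] <- 0; next }
    if (is.na(a) || is.na(b)) { db[j] <- 1; next }
    guard <- if (is.null(eps)) unname(WDD_FLOORS[FEATURE_NAMES[j]]) else eps
    db[j] <- min(abs(a - b) / max(abs(a), abs(b), guard), 1)
  }
  for (j in c(wdd_boolean_idx, wdd_categorical_idx)) {
    a <- beta[[FEATURE_NAMES[j]]]
    b <- beta_hat[[FEATURE_NAMES[j]]]
    db[j] <- as.numeric(!identical(a, b))
  }
  sum(WDD_WEIGHTS * db^2) / sum(WDD_WEIGHTS) * 100
}

#' Full fidelity report for an encoded record
#'
#' Compares an original uniform record against its reconstruction: global
#' and per-region PRD with peak-to-peak errors, compression ratio (when the
#' non-uniform record is supplied) and the mean per-beat WDD.
#'
#' @param original,decoded uniform records on the same grid.
#' @param annotations [beat_annotations] used for the regional metrics and
#'   feature extraction.
#' @param nu optional `nuecg` for the compression ratio.
#' @param lead lead used for feature extraction.
#' @return A list of class `metrics_report` with elements `prd_global`,
#'   `prd_per_region`, `ptp_error_uv`, `cr` and `wdd`.
#' @export
evaluate_codec <- function(original, decoded, annotations, nu = NULL,
                           lead = 1) {
  lp <- local_prd(original, decoded, annotations)
  feats_o <- extract_features_all(original, annotations, lead = lead)
  feats_d <- extract_features_all(decoded, annotations, lead = lead)
  wdds <- mapply(wdd, feats_o, feats_d)
  rep <- list(
    prd_global = prd(original, decoded),
    prd_per_region = lp$prd,
    ptp_error_uv = lp$ptp_uv_global,
    ptp_per_region_uv = lp$ptp_uv,
    cr = if (!is.null(nu)) compression_ratio(original, nu) else NA_real_,
    wdd = mean(wdds))
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Adaptive sampling fidelity report\n")
  cat(sprintf("  Compression ratio      %s\n",
              ifelse(is.na(x$cr), "-", sprintf("%.2f", x$cr))))
  cat(sprintf("  PRD [%%] global         %.3f (%.1f uV ptp)\n",
              x$prd_global, x$ptp_error_uv))
  lab <- c(P = "within P-wave", QRS = "within QRS complex",
           T = "within T-wave", out = "out of waves")
  for (r in names(lab))
    cat(sprintf("      %-18s %s (%s uV ptp)\n", lab[r],
                ifelse(is.na(x$prd_per_region[r]), "-",
                       sprintf("%.3f", x$prd_per_region[r])),
                ifelse(is.na(x$ptp_per_region_uv[r]), "-",
                       sprintf("%.1f", x$ptp_per_region_uv[r]))))
  cat(sprintf("  WDD [%%]                %.3f\n", x$wdd))
  invisible(x)
}
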