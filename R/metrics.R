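as_signal_matrix <- function(x) {
  if (inherits(x, "uniform_ecg")) x$signal
  else if (is.vector(x)) matrix(as.numeric(x), ncol = 1)
  else as.matrix(x)
}

#' Percent root-mean-square difference (PRD)
#'
#' `PRD = sqrt(sum((x1 - x2)^2) / sum(x1^2)) * 100`, computed without mean
#' subtraction. Multi-lead inputs are pooled over all leads.
#'
#' @param x1 reference signal: numeric vector, matrix or [uniform_ecg].
#' @param x2 comparison signal of identical size.
#' @return PRD in percent.
#' @examples
#' prd(c(3, 4), c(0, 0))  # 100
#' @export
prd <- function(x1, x2) {
  x1 <- as_signal_matrix(x1); x2 <- as_signal_matrix(x2)
  if (!all(dim(x1) == dim(x2)))
    stop("signals must have identical dimensions", call. = FALSE)
  den <- sum(x1^2)
  if (den == 0)
    stop("PRD undefined for an all-zero reference", call. = FALSE)
  sqrt(sum((x1 - x2)^2) / den) * 100
}

region_masks <- function(annotations, n) {
  pos <- seq_len(n) - 1
  p <- qrs <- tw <- rep(FALSE, n)
  for (i in seq_len(nrow(annotations))) {
    b <- as.numeric(annotations[i, c("p_on", "p_end", "qrs_on",
                                     "qrs_end", "t_end")])
    p <- p | (pos >= b[1] & pos <= b[2])
    qrs <- qrs | (pos >= b[3] & pos <= b[4])
    tw <- tw | (pos > b[4] & pos <= b[5])
  }
  list(P = p, QRS = qrs, T = tw, out = !(p | qrs | tw))
}

#' Region-wise PRD and peak-to-peak error
#'
#' PRD restricted to the union of P-wave regions (P-onset to P-end), QRS
#' regions (QRS-onset to QRS-end), T regions (QRS-end to T-end; no T-onset
#' fiducial exists) and the remaining out-of-wave samples, pooled over all
#' leads. The distortion is also reported as the average per-beat
#' peak-to-peak error in microvolts for compatibility with
#' interpretive-electrocardiograph performance limits.
#'
#' @param x1 reference record ([uniform_ecg], matrix or vector, microvolts).
#' @param x2 reconstructed record of identical size.
#' @param annotations [beat_annotations] on `x1`'s grid.
#' @param resolution_uv conversion factor applied to amplitudes before
#'   reporting microvolt errors (1 when signals are already in microvolts;
#'   pass the LSB size when signals are in converter units).
#' @return A list of class `local_prd` with elements `prd` (named vector
#'   over `P`, `QRS`, `T`, `out`; `NA` for an empty region), `ptp_uv`
#'   (matching average peak-to-peak errors) and `ptp_uv_global`.
#' @export
local_prd <- function(x1, x2, annotations, resolution_uv = 1) {
  x1 <- as_signal_matrix(x1); x2 <- as_signal_matrix(x2)
  if (!all(dim(x1) == dim(x2)))
    stop("signals must have identical dimensions", call. = FALSE)
  stopifnot(is_beat_annotations(annotations))
  n <- nrow(x1)
  if (nrow(annotations) > 0 &&
      max(annotations$t_end) > n - 1 + 1e-9)
    stop("annotations extend beyond the record", call. = FALSE)
  masks <- region_masks(annotations, n)
  err <- (x1 - x2) * resolution_uv

  prds <- vapply(masks, function(m) {
    if (!any(m)) return(NA_real_)
    den <- sum(x1[m, , drop = FALSE]^2)
    if (den == 0) return(NA_real_)
    sqrt(sum((x1[m, , drop = FALSE] - x2[m, , drop = FALSE])^2) / den) * 100
  }, 0)

  # average per-beat, per-lead peak-to-peak error per region
  ptp <- c(P = NA_real_, QRS = NA_real_, T = NA_real_, out = NA_real_)
  pos <- seq_len(n) - 1
  reg_bounds <- function(b, region) switch(region,
    P = c(b[1], b[2]), QRS = c(b[3], b[4]), T = c(b[4], b[5]), NULL)
  for (region in c("P", "QRS", "T")) {
    vals <- c()
    for (i in seq_len(nrow(annotations))) {
      b <- as.numeric(annotations[i, c("p_on", "p_end", "qrs_on",
                                       "qrs_end", "t_end")])
      rb <- reg_bounds(b, region)
      sel <- pos >= rb[1] & pos <= rb[2]
      if (!any(sel)) next
      e <- err[sel, , drop = FALSE]
      vals <- c(vals, apply(e, 2, function(v) diff(range(v))))
    }
    if (length(vals)) ptp[region] <- mean(vals)
  }
  if (any(masks$out)) {
    e <- err[masks$out, , drop = FALSE]
    ptp["out"] <- mean(apply(e, 2, function(v) diff(range(v))))
  }
  structure(list(prd = prds, ptp_uv = ptp,
                 ptp_uv_global = mean(apply(err, 2,
                                            function(v) diff(range(v))))),
            class = "local_prd")
}

#' Compression ratio of the non-uniform representation
#'
#' `CR = (N * L * sr) / (M * L * sr + M * q)`: the uniform record's bit
#' volume over the non-uniform sample values plus the shared interval side
#' channel (`q` bits per code). Headers are excluded on both sides.
#'
#' @param original the uniform [uniform_ecg] the record was encoded from.
#' @param nu the `nuecg` encoding of the same span.
#' @param sr bits per sample of the uniform original (default: the
#'   non-uniform record's own bit depth).
#' @return The compression ratio (may be below 1 when the side channel
#'   outweighs the sample savings).
#' @export
compression_ratio <- function(original, nu, sr = nu$bit_depth) {
  stopifnot(inherits(original, "uniform_ecg"), inherits(nu, "nuecg"))
  n <- n_samples(original)
  if (nu$n_samples_uniform != n)
    stop("records do not cover the same span", call. = FALSE)
  l <- n_leads(original)
  if (ncol(nu$values) != l)
    stop("lead counts differ", call. = FALSE)
  m <- length(nu$codes)
  (n * l * sr) / (m * l * sr + m * nu$policy$quant_bits)
}

#' @rdname compression_ratio
#' @param n_leads,fs,bits uniform stream parameters.
#' @return `uniform_stream_bps` returns the bit rate of the uniform record
#'   in bits per second.
#' @export
uniform_stream_bps <- function(n_leads, fs, bits) n_leads * fs * bits

#' Predicted per-lead output stream from a relevance template
#'
#' Approximates the per-lead bit rate of the adaptive representation from
#' the template alone: `d = (fm + (fs - fm) * bl * sum(MRF)) * sr`, where
#' `bl` is the bin length in seconds. The estimate assumes
#' duration-normalized heartbeats; with slow rhythms the true rate is lower
#' (long floors between beats) and with fast rhythms higher.
#'
#' @param template an [mrf_template].
#' @param policy a [sampling_policy].
#' @param sr bits per sample.
#' @return Estimated bits per second for one lead.
#' @export
estimate_stream <- function(template, policy, sr = 12) {
  stopifnot(inherits(template, "mrf_template"))
  (policy$fm + (policy$fs - policy$fm) *
     template$bin_length_s * sum(template$values)) * sr
}

#' Finite-record Beurling-type sampling density
#'
#' The lower uniform density of a sampling set is estimated on a finite
#' record as the minimum, over all windows of length `window_r` inside the
#' record span, of the number of samples in the window divided by the window
#' length. A density above twice the signal bandwidth guarantees stable
#' reconstruction of bandlimited signals.
#'
#' @param sample_times increasing sample times, seconds.
#' @param window_r window length, seconds; must not exceed the record span.
#' @return Estimated density, samples per second.
#' @export
beurling_density <- function(sample_times, window_r) {
  sample_times <- as.numeric(sample_times)
  if (length(sample_times) < 2)
    stop("need at least two samples", call. = FALSE)
  if (is.unsorted(sample_times, strictly = TRUE))
    stop("sample times must be strictly increasing", call. = FALSE)
  span <- diff(range(sample_times))
  if (window_r > span)
    stop("window longer than the record span", call. = FALSE)
  t0 <- sample_times[1]
  tN <- sample_times[length(sample_times)]
  # candidate window starts: each sample time and just after it
  starts <- c(sample_times, sample_times + 1e-12)
  starts <- starts[starts <= tN - window_r + 1e-12]
  if (length(starts) == 0) starts <- t0
  counts <- vapply(starts, function(y)
    sum(sample_times >= y & sample_times <= y + window_r), 0)
  min(counts) / window_r
}
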