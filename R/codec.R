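#' Adaptive sampling policy
#'
#' Fixes the native rate `fs`, the minimum usable local rate `fm` and the
#' side-channel word size. The local sampling interval ranges over
#' `[Ts, Tm] = [1/fs, 1/fm]` and is quantized to `P = 2^quant_bits` levels on
#' the grid `Ts + p * (Tm - Ts) / P`, `p = 0 .. P-1`; for the reference
#' configuration (500 Hz, 100 Hz, 6 bits) this is a 0.125 ms step between
#' 2 ms and 9.875 ms, and code 0 is the native interval.
#'
#' @param fs native sampling rate, Hz.
#' @param fm minimum local sampling rate, Hz; `0 < fm < fs`.
#' @param quant_bits side-channel bits per interval code (default 6).
#' @return An object of class `sampling_policy` with derived fields `Ts`,
#'   `Tm`, `P` and `step` (seconds per code increment).
#' @export
sampling_policy <- function(fs = 500, fm = 100, quant_bits = 6) {
  if (!(fm > 0 && fm < fs))
    stop("need 0 < fm < fs", call. = FALSE)
  if (quant_bits < 1 || quant_bits > 16 || quant_bits != round(quant_bits))
    stop("quant_bits must be an integer in 1..16", call. = FALSE)
  Ts <- 1 / fs
  Tm <- 1 / fm
  P <- 2L^as.integer(quant_bits)
  structure(
    list(fs = fs, fm = fm, quant_bits = as.integer(quant_bits),
         Ts = Ts, Tm = Tm, P = P, step = (Tm - Ts) / P),
    class = "sampling_policy")
}

#' @export
print.sampling_policy <- function(x, ...) {
  cat(sprintf(
    "sampling_policy: fs=%g Hz, fm=%g Hz, %d-bit codes (P=%d, step=%g ms)\n",
    x$fs, x$fm, x$quant_bits, x$P, x$step * 1000))
  invisible(x)
}

#' Interval law: relevance to local sampling interval
#'
#' The local sampling interval is linear in relevance,
#' `ls = Tm + (Ts - Tm) * r`: maximum relevance 1 samples at the native
#' interval `Ts`, relevance 0 at the longest interval `Tm`. `code_from_ls`
#' quantizes an interval to the policy's code grid and `ls_from_code` maps
#' codes back to interval durations.
#'
#' @param relevance relevance values in `[0, 1]`.
#' @param policy a [sampling_policy].
#' @return seconds (`ls_from_relevance`, `ls_from_code`) or integer codes in
#'   `0 .. P-1` (`code_from_ls`).
#' @export
ls_from_relevance <- function(relevance, policy) {
  policy$Tm + (policy$Ts - policy$Tm) * relevance
}

#' @rdname ls_from_relevance
#' @param ls local sampling intervals, seconds.
#' @export
code_from_ls <- function(ls, policy) {
  p <- round((ls - policy$Ts) / policy$step)
  as.integer(pmin(pmax(p, 0), policy$P - 1))
}

#' @rdname ls_from_relevance
#' @param code integer interval codes.
#' @export
ls_from_code <- function(code, policy) {
  policy$Ts + code * policy$step
}

#' Derive the non-uniform sampling schedule from an adapted MRF
#'
#' Starting at time 0, the local interval is evaluated from the relevance at
#' the current position, quantized to the policy's code grid, and the clock
#' advances by the quantized interval; the walk stops once the end of the
#' record span is passed. All emitted times therefore lie on sums of
#' quantized intervals and are exactly recoverable from the code stream.
#'
#' @param amrf per-sample relevance (an [adapt_mrf] result or any numeric
#'   vector in `[0, 1]`, one value per uniform sample).
#' @param policy a [sampling_policy].
#' @param fs sampling rate of the uniform grid the relevance lives on
#'   (defaults to `policy$fs`).
#' @return A data frame with columns `time` (seconds) and `code`.
#' @export
intervals_from_mrf <- function(amrf, policy, fs = policy$fs) {
  amrf <- as.numeric(amrf)
  n <- length(amrf)
  if (n < 2) stop("empty or degenerate adapted MRF", call. = FALSE)
  t_end <- (n - 1) / fs
  rel_at <- stats::approxfun((seq_len(n) - 1) / fs, amrf, rule = 2)
  # worst case one sample per native interval
  cap <- n + 2L
  times <- numeric(cap)
  codes <- integer(cap)
  m <- 0L
  t <- 0
  tol <- policy$Ts * 1e-6
  while (t <= t_end + tol) {
    m <- m + 1L
    ls <- ls_from_relevance(rel_at(t), policy)
    p <- code_from_ls(ls, policy)
    times[m] <- t
    codes[m] <- p
    t <- t + ls_from_code(p, policy)
  }
  data.frame(time = times[seq_len(m)], code = codes[seq_len(m)])
}

# --- time-varying anti-alias filter bank ------------------------------------

# Order-10 (11-tap) symmetric windowed-sinc low-pass kernel with unity DC
# gain and vanishing second moment; the moment correction makes the kernel
# reproduce cubic polynomials exactly in the filter interior while keeping a
# gentle low-pass roll-off. Code 0 (native rate) maps to the identity kernel.
aa_kernel <- function(code, policy, order = 10, cutoff_factor = 0.45) {
  if (code <= 0) {
    h <- numeric(order + 1)
    h[order / 2 + 1] <- 1
    return(h)
  }
  fs <- policy$fs
  fc <- cutoff_factor / ls_from_code(code, policy)
  k <- seq(-order / 2, order / 2)
  x <- 2 * fc / fs * k
  h0 <- 2 * fc / fs * ifelse(k == 0, 1, sin(pi * x) / (pi * x))
  h0 <- h0 * (0.54 + 0.46 * cos(2 * pi * k / (order + 2)))  # Hamming-type
  # constrain sum(h) = 1 and sum(k^2 h) = 0 (minimal L2 correction)
  A <- rbind(rep(1, order + 1), k^2)
  h0 + drop(t(A) %*% solve(A %*% t(A), c(1, 0) - A %*% h0))
}

aa_kernel_bank <- function(policy, order = 10, cutoff_factor = 0.45) {
  lapply(0:(policy$P - 1), function(p)
    aa_kernel(p, policy, order = order, cutoff_factor = cutoff_factor))
}

# cubic edge padding: extrapolate `npad` samples at each end through the
# outermost four samples, so polynomial inputs stay polynomial across edges
pad_cubic <- function(x, npad) {
  n <- length(x)
  stopifnot(n >= 4)
  V <- outer(0:3, 0:3, `^`)  # local coordinates keep the system well-posed
  cl <- solve(V, x[1:4])
  cr <- solve(V, x[(n - 3):n])
  left <- drop(outer(seq(-npad, -1), 0:3, `^`) %*% cl)
  right <- drop(outer(seq(4, 3 + npad), 0:3, `^`) %*% cr)
  c(left, x, right)
}

#' Time-varying anti-alias low-pass filtering
#'
#' Each output sample is the input convolved with an order-10 symmetric
#' windowed-sinc kernel whose cutoff is `cutoff_factor` (default 0.45) times
#' the local sampling rate at that sample, selected from a precomputed bank
#' of `P` kernels, one per interval code. The symmetric kernel is zero-phase,
#' so the output stays aligned with the input; record edges are handled by
#' local cubic extrapolation. Samples coded at the native rate (code 0) pass
#' through unfiltered.
#'
#' @param ecg a [uniform_ecg] sampled at `policy$fs`.
#' @param codes integer vector, one interval code per uniform sample (e.g.
#'   `code_from_ls(ls_from_relevance(amrf, policy), policy)`). Codes outside
#'   `0 .. P-1` are clipped with a warning.
#' @param policy a [sampling_policy].
#' @param cutoff_factor cutoff as a fraction of the local sampling rate.
#' @return A [uniform_ecg] with the filtered signal.
#' @export
antialias <- function(ecg, codes, policy, cutoff_factor = 0.45) {
  stopifnot(inherits(ecg, "uniform_ecg"))
  n <- n_samples(ecg)
  codes <- as.integer(round(codes))
  if (length(codes) == 1) codes <- rep(codes, n)
  if (length(codes) != n)
    stop("'codes' must supply one interval code per sample", call. = FALSE)
  if (any(codes < 0 | codes > policy$P - 1)) {
    warning("interval codes outside 0..P-1 clipped")
    codes <- pmin(pmax(codes, 0L), policy$P - 1L)
  }
  order <- 10L
  half <- order %/% 2L
  used <- sort(unique(codes))
  out <- ecg$signal
  for (l in seq_len(n_leads(ecg))) {
    xp <- pad_cubic(ecg$signal[, l], half)
    col <- numeric(n)
    for (p in used) {
      sel <- codes == p
      if (p == 0) { col[sel] <- ecg$signal[sel, l]; next }
      h <- aa_kernel(p, policy, order = order,
                     cutoff_factor = cutoff_factor)
      y <- stats::filter(xp, h, sides = 2)
      col[sel] <- y[half + which(sel)]
    }
    out[, l] <- col
  }
  uniform_ecg(out, fs = ecg$fs, lead_labels = ecg$lead_labels,
              resolution_uv = ecg$resolution_uv)
}

#' Encode a uniform ECG into its non-uniform adaptive representation
#'
#' The encoder chain: wave delineation (unless annotations are supplied),
#' beat-by-beat projection of the relevance template onto the detected
#' borders ([adapt_mrf]), derivation of the quantized interval schedule
#' ([intervals_from_mrf]), time-varying anti-alias filtering ([antialias]),
#' and cubic-spline interpolation of every lead at the non-uniform times.
#' All leads share one interval-code stream.
#'
#' If the record has a finite amplitude resolution, sample values are
#' quantized back to the ADC grid at `bit_depth` bits; otherwise they are
#' kept as doubles (exact test signals).
#'
#' @param ecg a [uniform_ecg] sampled at `policy$fs`.
#' @param template an [mrf_template] (default [default_gmrf()]).
#' @param policy a [sampling_policy]; its `fs` must match the record.
#' @param annotations optional [beat_annotations] to use instead of the
#'   built-in delineator (e.g. reference borders).
#' @param amrf optional per-sample relevance overriding the delineate+project
#'   stage entirely.
#' @param bit_depth bits per stored sample value for quantized records.
#' @param apply_antialias set `FALSE` to skip the anti-alias stage (pure
#'   spline resampling).
#' @return An object of class `nuecg`.
#' @export
encode_ecg <- function(ecg, template = default_gmrf(),
                       policy = sampling_policy(fs = ecg$fs),
                       annotations = NULL, amrf = NULL, bit_depth = 12,
                       apply_antialias = TRUE) {
  stopifnot(inherits(ecg, "uniform_ecg"))
  if (abs(policy$fs - ecg$fs) > 1e-9)
    stop("policy fs does not match record fs", call. = FALSE)
  n <- n_samples(ecg)
  if (is.null(amrf)) {
    if (is.null(annotations)) {
      beats <- detect_beats(ecg)
      if (length(beats) == 0) {
        warning("no beats found; coding whole record at maximum relevance")
        amrf <- rep(1, n)
      } else {
        annotations <- delineate(ecg, beats)
      }
    }
    if (is.null(amrf))
      amrf <- adapt_mrf(template, annotations, n, ecg$fs)
  } else {
    amrf <- rep_len(as.numeric(amrf), n)
  }

  sched <- intervals_from_mrf(amrf, policy)
  sample_codes <- code_from_ls(ls_from_relevance(amrf, policy), policy)
  filtered <- if (apply_antialias) antialias(ecg, sample_codes, policy)
              else ecg

  t_u <- (seq_len(n) - 1) / ecg$fs
  m <- nrow(sched)
  values <- matrix(0, m, n_leads(ecg))
  for (l in seq_len(n_leads(ecg))) {
    sf <- stats::splinefun(t_u, filtered$signal[, l], method = "fmm")
    values[, l] <- sf(sched$time)
  }

  res <- ecg$resolution_uv
  if (is.finite(res)) {
    half_range <- 2^(bit_depth - 1)
    adu <- round(values / res)
    adu <- pmin(pmax(adu, -half_range), half_range - 1)
    values <- adu
    storage.mode(values) <- "integer"
    fmt <- "int"
  } else {
    bit_depth <- 64
    fmt <- "float"
  }

  structure(
    list(policy = policy, lead_labels = ecg$lead_labels,
         bit_depth = as.integer(bit_depth), value_format = fmt,
         resolution_uv = res, codes = sched$code, values = values,
         n_samples_uniform = as.integer(n)),
    class = "nuecg")
}

#' @export
print.nuecg <- function(x, ...) {
  cat(sprintf(
    "nuecg: %d non-uniform samples x %d leads (from %d uniform @ %g Hz)\n",
    length(x$codes), ncol(x$values), x$n_samples_uniform, x$policy$fs))
  cat(sprintf("  side channel: %d-bit codes, values: %s @ %d bits\n",
              x$policy$quant_bits, x$value_format, x$bit_depth))
  invisible(x)
}

#' Implied sample times of a non-uniform record
#'
#' Times are reconstructed purely from the shared code stream:
#' `t_1 = 0`, `t_m = t_{m-1} + ls(code_{m-1})`.
#'
#' @param nu an `nuecg` object.
#' @return Numeric vector of sample times, seconds, strictly increasing.
#' @export
nuecg_times <- function(nu) {
  stopifnot(inherits(nu, "nuecg"))
  m <- length(nu$codes)
  if (m == 0) return(numeric(0))
  if (any(nu$codes < 0 | nu$codes > nu$policy$P - 1))
    stop("corrupt code stream: codes outside alphabet", call. = FALSE)
  cumsum(c(0, ls_from_code(nu$codes[-m], nu$policy)))
}

#' @rdname nuecg_times
#' @export
nuecg_values_uv <- function(nu) {
  stopifnot(inherits(nu, "nuecg"))
  if (nu$value_format == "int") nu$values * nu$resolution_uv
  else nu$values
}

#' Decode a non-uniform record back to a uniform ECG
#'
#' Implied sample times are reconstructed from the interval-code stream, a
#' cubic spline is fitted per lead through the non-uniform samples, and the
#' spline is evaluated on the uniform grid at the policy's native rate over
#' the original record span.
#'
#' @param nu an `nuecg` object from [encode_ecg] or [read_nuecg].
#' @return A [uniform_ecg].
#' @export
decode_ecg <- function(nu) {
  stopifnot(inherits(nu, "nuecg"))
  times <- nuecg_times(nu)
  if (length(times) < 4)
    stop("too few non-uniform samples to reconstruct", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("corrupt code stream: implied times not increasing", call. = FALSE)
  vals <- nuecg_values_uv(nu)
  n <- nu$n_samples_uniform
  grid <- (seq_len(n) - 1) / nu$policy$fs
  out <- matrix(0, n, ncol(vals))
  for (l in seq_len(ncol(vals))) {
    sf <- stats::splinefun(times, vals[, l], method = "fmm")
    out[, l] <- sf(grid)
  }
  uniform_ecg(out, fs = nu$policy$fs, lead_labels = nu$lead_labels,
              resolution_uv = NA_real_)
}
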