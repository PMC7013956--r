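#' Uniformly sampled multi-lead ECG
#'
#' Container for a uniformly sampled multi-lead ECG record. Amplitudes are
#' held in microvolts; when the record originates from an ADC the amplitude
#' resolution (microvolts per least significant bit) is carried along so that
#' downstream quantization and error reporting can work in converter units.
#'
#' Throughout the package, sample positions are 0-based fractional sample
#' numbers on the uniform grid; time in seconds is `position / fs`.
#'
#' @param signal numeric matrix, one column per lead, amplitudes in microvolts
#'   (a vector is treated as a single lead).
#' @param fs sampling rate in Hz.
#' @param lead_labels character vector of lead names; defaults to the standard
#'   12-lead names when twelve columns are supplied, else `L1`, `L2`, ...
#' @param resolution_uv microvolts per LSB of the originating converter, or
#'   `NA` for an exact (unquantized) signal such as an analytic test waveform.
#' @return An object of class `uniform_ecg`: a list with elements `signal`,
#'   `fs`, `lead_labels`, `resolution_uv`.
#' @examples
#' x <- uniform_ecg(sin(2 * pi * 5 * (0:999) / 500), fs = 500)
#' n_samples(x)
#' @export
uniform_ecg <- function(signal, fs, lead_labels = NULL, resolution_uv = NA_real_) {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number", call. = FALSE)
  if (any(!is.finite(signal)))
    stop("'signal' contains non-finite values", call. = FALSE)
  nl <- ncol(signal)
  if (is.null(lead_labels)) {
    lead_labels <- if (nl == 12) std_12_leads() else paste0("L", seq_len(nl))
  }
  if (length(lead_labels) != nl)
    stop("'lead_labels' length does not match number of leads", call. = FALSE)
  structure(
    list(signal = signal, fs = as.numeric(fs),
         lead_labels = as.character(lead_labels),
         resolution_uv = as.numeric(resolution_uv)),
    class = "uniform_ecg")
}

std_12_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' @rdname uniform_ecg
#' @param x a `uniform_ecg` object.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "uniform_ecg"))
  nrow(x$signal)
}

#' @rdname uniform_ecg
#' @export
n_leads <- function(x) {
  stopifnot(inherits(x, "uniform_ecg"))
  ncol(x$signal)
}

#' @rdname uniform_ecg
#' @export
duration_s <- function(x) {
  stopifnot(inherits(x, "uniform_ecg"))
  (nrow(x$signal) - 1) / x$fs
}

#' @export
print.uniform_ecg <- function(x, ...) {
  cat(sprintf("uniform_ecg: %d samples x %d leads @ %g Hz (%.3f s)\n",
              n_samples(x), n_leads(x), x$fs, duration_s(x)))
  cat(sprintf("  leads: %s\n", paste(x$lead_labels, collapse = ", ")))
  if (is.finite(x$resolution_uv))
    cat(sprintf("  amplitude resolution: %.6g uV/LSB\n", x$resolution_uv))
  invisible(x)
}

#' Read and write uniform ECG records as CSV
#'
#' The CSV layout is one column per lead with a header row of lead labels,
#' preceded by a single comment line carrying the sampling rate and (when
#' known) the amplitude resolution, e.g.
#' `# fs=500 resolution_uv=2.44140625`.
#'
#' @param ecg a [uniform_ecg] object.
#' @param path file path.
#' @return `read_ecg_csv` returns a [uniform_ecg]; `write_ecg_csv` returns
#'   `path` invisibly.
#' @export
write_ecg_csv <- function(ecg, path) {
  stopifnot(inherits(ecg, "uniform_ecg"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- sprintf("# fs=%s", format(ecg$fs, digits = 15))
  if (is.finite(ecg$resolution_uv))
    meta <- paste0(meta, sprintf(" resolution_uv=%s",
                                 format(ecg$resolution_uv, digits = 15)))
  writeLines(meta, con)
  writeLines(paste(ecg$lead_labels, collapse = ","), con)
  utils::write.table(ecg$signal, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write uniform ECG records in the binary container
#'
#' A uniformly sampled record is the degenerate case of the non-uniform
#' container (every interval at the native rate, code 0), so these wrappers
#' store it through [write_nuecg]/[read_nuecg]. The round trip is exact:
#' spline knots coincide with the uniform grid.
#'
#' @param ecg a [uniform_ecg].
#' @param path file path.
#' @export
write_ecg_bin <- function(ecg, path) {
  stopifnot(inherits(ecg, "uniform_ecg"))
  nu <- encode_ecg(ecg, amrf = rep(1, n_samples(ecg)),
                   policy = sampling_policy(fs = ecg$fs, fm = ecg$fs / 5),
                   apply_antialias = FALSE)
  write_nuecg(nu, path)
}

#' @rdname write_ecg_bin
#' @export
read_ecg_bin <- function(path) {
  nu <- read_nuecg(path)
  if (any(nu$codes != 0))
    stop("not a uniform record: non-native interval codes present",
         call. = FALSE)
  dec <- decode_ecg(nu)
  dec$resolution_uv <- nu$resolution_uv
  dec
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  lines <- readLines(path, n = 2)
  if (length(lines) < 2 || !startsWith(lines[1], "#"))
    stop("not an ECG CSV: missing '# fs=...' metadata line", call. = FALSE)
  meta <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
  kv <- strsplit(meta, "=")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  if (!"fs" %in% keys) stop("ECG CSV metadata lacks fs", call. = FALSE)
  fs <- as.numeric(vals[keys == "fs"])
  res <- if ("resolution_uv" %in% keys)
    as.numeric(vals[keys == "resolution_uv"]) else NA_real_
  labels <- strsplit(lines[2], ",")[[1]]
  dat <- utils::read.csv(path, skip = 2, header = FALSE)
  sig <- as.matrix(dat)
  dimnames(sig) <- NULL
  uniform_ecg(sig, fs = fs, lead_labels = labels, resolution_uv = res)
}
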