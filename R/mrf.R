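#' Medical relevance function templates
#'
#' An MRF template is a relevance profile over a duration-normalized heartbeat
#' derived from the gaze statistics of expert readers: one value in `[0, 1]`
#' per time bin (default bin length 0.032 s), together with five landmark
#' coordinates marking P-onset, P-end, QRS-onset, QRS-end and T-end on the
#' template grid. The landmarks anchor the piecewise-linear projection of the
#' template onto each actual heartbeat (see [adapt_mrf]).
#'
#' Template coordinates are expressed as sample indices on the template's own
#' grid (`grid_fs` samples per second, default 500), so a 0.032 s bin spans 16
#' grid samples and bin `j` covers grid samples `[(j-1)*16, j*16)`.
#'
#' @param values numeric vector of per-bin relevance, non-negative; values
#'   above 1 are normalized by the maximum so the template lies in `[0, 1]`.
#' @param landmarks five strictly increasing template-grid coordinates
#'   (P-onset, P-end, QRS-onset, QRS-end, T-end) inside the template support.
#' @param bin_length_s bin length in seconds (default 0.032).
#' @param grid_fs template grid rate in samples per second.
#' @param name template label.
#' @return An object of class `mrf_template`.
#' @export
mrf_template <- function(values, landmarks, bin_length_s = 0.032,
                         grid_fs = 500, name = "custom") {
  values <- as.numeric(values)
  if (length(values) < 2 || any(!is.finite(values)))
    stop("template values must be a finite numeric vector", call. = FALSE)
  if (any(values < 0))
    stop("template values must be non-negative", call. = FALSE)
  mx <- max(values)
  if (mx > 1) values <- values / mx  # scale down; [0,1] inputs pass as-is
  landmarks <- as.numeric(landmarks)
  if (length(landmarks) != 5)
    stop("exactly five landmarks are required (P-on, P-end, QRS-on, QRS-end, T-end)",
         call. = FALSE)
  if (is.unsorted(landmarks, strictly = TRUE))
    stop("landmarks must be strictly increasing", call. = FALSE)
  len <- length(values) * bin_length_s * grid_fs
  if (landmarks[1] < 0 || landmarks[5] > len)
    stop("landmarks must lie within the template support", call. = FALSE)
  structure(
    list(name = as.character(name), values = values,
         bin_length_s = bin_length_s, grid_fs = grid_fs,
         landmarks = landmarks),
    class = "mrf_template")
}

#' @export
print.mrf_template <- function(x, ...) {
  cat(sprintf("mrf_template '%s': %d bins of %g s (grid %g Hz)\n",
              x$name, length(x$values), x$bin_length_s, x$grid_fs))
  cat(sprintf("  landmarks (P-on, P-end, QRS-on, QRS-end, T-end): %s\n",
              paste(format(x$landmarks), collapse = ", ")))
  invisible(x)
}

#' Evaluate an MRF template at template-grid coordinates
#'
#' Relevance between the 0.032 s bins is linearly interpolated between bin
#' centers; coordinates beyond the first or last bin center hold the edge
#' value, which is also the template's inter-beat floor.
#'
#' @param template an [mrf_template].
#' @param a numeric vector of template-grid coordinates.
#' @return Relevance values in `[0, 1]`, same length as `a`.
#' @export
mrf_value <- function(template, a) {
  spb <- template$bin_length_s * template$grid_fs
  centers <- (seq_along(template$values) - 0.5) * spb
  stats::approx(centers, template$values, xout = a, rule = 2)$y
}

#' Built-in relevance templates
#'
#' `default_gmrf()` returns the package's generalized MRF: an approximation of
#' the expert gaze-density histogram over a normalized heartbeat, with the
#' reference landmark set (106, 196, 246, 338, 672) on a 500 Hz template grid.
#' The profile peaks at 1 over the QRS complex, carries moderate relevance
#' over the P and T waves, and decays to a 0.05 floor between beats.
#'
#' `smrf_qrs_roi()` returns a specific MRF variant with a region of interest
#' focused on the end of the QRS complex and the ST segment (e.g., for
#' infarct or conduction-defect monitoring); it trades relevance in the
#' P-wave vicinity for accuracy around QRS-end.
#'
#' Both profiles are package-authored approximations of perception-derived
#' curves and are meant to be replaced by user-supplied templates
#' (see [read_mrf_template]).
#'
#' @return An [mrf_template].
#' @export
default_gmrf <- function() {
  v <- c(0.05, 0.05, 0.06, 0.06, 0.08,
         0.12, 0.20, 0.30, 0.38, 0.42,
         0.45, 0.42, 0.35, 0.28, 0.40,
         0.70, 0.95, 1.00, 1.00, 0.95,
         0.85, 0.70, 0.55, 0.45, 0.40,
         0.38, 0.36, 0.35, 0.35, 0.36,
         0.38, 0.40, 0.42, 0.44, 0.45,
         0.44, 0.40, 0.34, 0.28, 0.20,
         0.14, 0.10, 0.07, 0.05, 0.05,
         0.05, 0.05, 0.05, 0.05, 0.05)
  mrf_template(v, landmarks = c(106, 196, 246, 338, 672),
               name = "gmrf_default")
}

#' @rdname default_gmrf
#' @export
smrf_qrs_roi <- function() {
  v <- c(0.05, 0.05, 0.05, 0.05, 0.05,
         0.06, 0.08, 0.10, 0.12, 0.12,
         0.12, 0.10, 0.10, 0.12, 0.30,
         0.60, 0.85, 0.95, 1.00, 1.00,
         1.00, 1.00, 0.95, 0.85, 0.70,
         0.55, 0.45, 0.40, 0.38, 0.36,
         0.36, 0.38, 0.40, 0.40, 0.38,
         0.35, 0.30, 0.25, 0.20, 0.15,
         0.10, 0.08, 0.06, 0.05, 0.05,
         0.05, 0.05, 0.05, 0.05, 0.05)
  mrf_template(v, landmarks = c(106, 196, 246, 338, 672),
               name = "smrf_qrs_roi")
}

#' Read and write MRF templates
#'
#' JSON files carry fields `name`, `bin_length_s`, `grid_fs`, `values` and
#' `landmarks`; CSV files carry one `value` column with the remaining fields
#' in `# key=value` comment lines. The built-in names `"gmrf_default"` and
#' `"smrf_qrs_roi"` are also accepted by `read_mrf_template`.
#'
#' @param template an [mrf_template].
#' @param path file path (`.json` or `.csv`), or a built-in template name.
#' @export
write_mrf_template <- function(template, path) {
  stopifnot(inherits(template, "mrf_template"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# name=%s bin_length_s=%s grid_fs=%s landmarks=%s",
                       template$name,
                       format(template$bin_length_s, digits = 15),
                       format(template$grid_fs, digits = 15),
                       paste(format(template$landmarks, digits = 15),
                             collapse = ";")), con)
    writeLines("value", con)
    writeLines(format(template$values, digits = 15), con)
  } else {
    jsonlite::write_json(
      list(name = template$name, bin_length_s = template$bin_length_s,
           grid_fs = template$grid_fs, values = template$values,
           landmarks = template$landmarks),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_mrf_template
#' @export
read_mrf_template <- function(path) {
  builtin <- c(gmrf_default = default_gmrf, smrf_qrs_roi = smrf_qrs_roi)
  if (path %in% names(builtin)) return(builtin[[path]]())
  if (!file.exists(path))
    stop("no such template file or built-in name: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    first <- readLines(path, n = 1)
    if (!startsWith(first, "#"))
      stop("template CSV lacks '# key=value' metadata line", call. = FALSE)
    meta <- strsplit(sub("^#\\s*", "", first), "\\s+")[[1]]
    kv <- strsplit(meta, "=")
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, `[`, "", 2)
    need <- c("bin_length_s", "landmarks")
    if (!all(need %in% keys))
      stop("template CSV metadata lacks ", paste(setdiff(need, keys),
                                                 collapse = ", "), call. = FALSE)
    values <- utils::read.csv(path, skip = 1)$value
    mrf_template(values,
                 landmarks = as.numeric(strsplit(vals[keys == "landmarks"],
                                                 ";")[[1]]),
                 bin_length_s = as.numeric(vals[keys == "bin_length_s"]),
                 grid_fs = if ("grid_fs" %in% keys)
                   as.numeric(vals[keys == "grid_fs"]) else 500,
                 name = if ("name" %in% keys) vals[keys == "name"] else "custom")
  } else {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("values", "landmarks", "bin_length_s")
    if (!all(need %in% names(d)))
      stop("template JSON lacks ", paste(setdiff(need, names(d)),
                                         collapse = ", "), call. = FALSE)
    mrf_template(d$values, landmarks = d$landmarks,
                 bin_length_s = d$bin_length_s,
                 grid_fs = if (!is.null(d$grid_fs)) d$grid_fs else 500,
                 name = if (!is.null(d$name)) d$name else "custom")
  }
}

#' Project an MRF template onto one annotated heartbeat
#'
#' Piecewise-linear landmark registration: a signal position `b` inside
#' border segment `[b_{k-1}, b_k]` maps to the template coordinate
#' `a(b) = a_{k-1} + (a_k - a_{k-1}) * (b - b_{k-1}) / (b_k - b_{k-1})`, so
#' landmark positions map exactly onto landmark coordinates and each segment
#' of the template is stretched or contracted to fit the actual wave
#' durations. Outside the landmark span the template is applied without
#' stretching (one signal sample step equals `grid_fs / fs` template samples),
#' so relevance decays along the template's own tails to its edge floor.
#'
#' An annotation that violates the border ordering is rejected: the whole
#' beat span is returned at maximum relevance (conservative fallback).
#'
#' @param template an [mrf_template].
#' @param borders numeric vector of five border positions (0-based samples).
#' @param positions sample positions (0-based, fractional allowed) at which
#'   to evaluate the adapted relevance.
#' @param fs sampling rate of the signal grid, Hz.
#' @return Relevance values in `[0, 1]` at `positions`.
#' @export
project_mrf <- function(template, borders, positions, fs) {
  stopifnot(inherits(template, "mrf_template"))
  borders <- as.numeric(borders)
  if (length(borders) != 5 || is.unsorted(borders, strictly = TRUE))
    return(rep(1, length(positions)))
  a_land <- template$landmarks
  ratio <- template$grid_fs / fs
  a <- numeric(length(positions))
  inside <- positions >= borders[1] & positions <= borders[5]
  if (any(inside)) {
    # piecewise-linear registration between consecutive landmarks
    seg <- findInterval(positions[inside], borders,
                        rightmost.closed = TRUE, all.inside = TRUE)
    b0 <- borders[seg]; b1 <- borders[seg + 1]
    a0 <- a_land[seg]; a1 <- a_land[seg + 1]
    a[inside] <- a0 + (a1 - a0) * (positions[inside] - b0) / (b1 - b0)
  }
  left <- positions < borders[1]
  a[left] <- a_land[1] - (borders[1] - positions[left]) * ratio
  right <- positions > borders[5]
  a[right] <- a_land[5] + (positions[right] - borders[5]) * ratio
  mrf_value(template, a)
}

#' Build the adapted MRF for a whole record
#'
#' Projects the template onto every annotated beat and combines the per-beat
#' contributions into one relevance value per uniform signal sample (pointwise
#' maximum where tails of neighboring beats overlap). Samples not reached by
#' any beat sit at the template's edge floor. Beats flagged by the delineator
#' are coded at maximum relevance over their span: the codec never
#' under-samples on uncertainty.
#'
#' @param template an [mrf_template].
#' @param annotations a [beat_annotations] data frame.
#' @param n_samples number of uniform samples in the record.
#' @param fs sampling rate, Hz.
#' @return Numeric vector of length `n_samples` with values in `[0, 1]`,
#'   class `adapted_mrf`.
#' @export
adapt_mrf <- function(template, annotations, n_samples, fs) {
  stopifnot(inherits(template, "mrf_template"))
  floor_val <- min(template$values[1],
                   template$values[length(template$values)])
  amrf <- rep(floor_val, n_samples)
  positions <- seq_len(n_samples) - 1
  if (is_beat_annotations(annotations) && nrow(annotations) > 0) {
    for (i in seq_len(nrow(annotations))) {
      b <- as.numeric(annotations[i, c("p_on", "p_end", "qrs_on",
                                       "qrs_end", "t_end")])
      if (isTRUE(annotations$flagged[i])) {
        lo <- max(1, floor(b[1]) + 1)
        hi <- min(n_samples, ceiling(b[5]) + 1)
        amrf[lo:hi] <- pmax(amrf[lo:hi], 1)
      } else {
        contrib <- project_mrf(template, b, positions, fs)
        amrf <- pmax(amrf, contrib)
      }
    }
  }
  structure(pmin(pmax(amrf, 0), 1), class = "adapted_mrf")
}
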