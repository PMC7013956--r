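#' Per-beat wave-border annotations
#'
#' Five fiducial points delimit the waves of each heartbeat: P-onset, P-end,
#' QRS-onset, QRS-end and T-end (T-onset is not a standard fiducial point).
#' Borders are 0-based fractional sample positions on the uniform grid and
#' must be strictly increasing within a beat and non-overlapping across
#' consecutive beats.
#'
#' @param borders numeric matrix (or data frame) with columns `p_on`, `p_end`,
#'   `qrs_on`, `qrs_end`, `t_end`, one row per beat.
#' @param flagged logical vector, one per beat; `TRUE` marks beats whose
#'   borders could not be fully resolved (downstream coding falls back to
#'   maximum relevance over the affected span).
#' @return A data frame of class `beat_annotations` with columns `beat_index`
#'   (0-based), the five border columns, and `flagged`.
#' @export
beat_annotations <- function(borders, flagged = NULL) {
  cols <- c("p_on", "p_end", "qrs_on", "qrs_end", "t_end")
  borders <- as.data.frame(borders)
  if (!all(cols %in% names(borders))) {
    if (ncol(borders) == 5) names(borders) <- cols
    else stop("borders must have columns ", paste(cols, collapse = ", "),
              call. = FALSE)
  }
  borders <- borders[cols]
  nb <- nrow(borders)
  if (is.null(flagged)) flagged <- rep(FALSE, nb)
  m <- as.matrix(borders)
  if (nb > 0) {
    flat <- as.numeric(t(m))
    if (is.unsorted(flat, strictly = TRUE))
      stop("wave borders must be strictly increasing within and across beats",
           call. = FALSE)
    if (any(m < 0)) stop("wave borders must be non-negative", call. = FALSE)
  }
  out <- cbind(data.frame(beat_index = seq_len(nb) - 1L), borders,
               data.frame(flagged = as.logical(flagged)))
  class(out) <- c("beat_annotations", "data.frame")
  out
}

#' @rdname beat_annotations
#' @param x object to test.
#' @export
is_beat_annotations <- function(x) inherits(x, "beat_annotations")

#' Read and write wave-border annotations as CSV
#'
#' One row per beat with columns `beat_index`, `p_on`, `p_end`, `qrs_on`,
#' `qrs_end`, `t_end` (sample units, 0-based, fractional allowed) and
#' `flagged`. The format is symmetric so that externally supplied reference
#' borders can be injected in place of the built-in delineator.
#'
#' @param ann a [beat_annotations] object.
#' @param path file path.
#' @export
write_annotations_csv <- function(ann, path) {
  stopifnot(is_beat_annotations(ann))
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  dat <- utils::read.csv(path)
  need <- c("p_on", "p_end", "qrs_on", "qrs_end", "t_end")
  if (!all(need %in% names(dat)))
    stop("annotation CSV lacks required border columns", call. = FALSE)
  flagged <- if ("flagged" %in% names(dat)) dat$flagged else NULL
  beat_annotations(dat[need], flagged = flagged)
}
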