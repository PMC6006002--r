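#' Organ labels recognised by the pipeline
#'
#' Activity-concentration samples are drawn over the kidneys, liver,
#' spleen, remainder of the body, tumors, and blood (the surrogate for
#' bone-marrow kinetics). `bone_marrow` additionally appears as a dose
#' *target* but never as a measured sample.
#'
#' @format Character vectors.
#' @export
SAMPLE_ORGANS <- c("kidneys", "liver", "spleen", "remainder", "tumor", "blood")

#' @rdname SAMPLE_ORGANS
#' @export
DOSE_TARGETS <- c("kidneys", "liver", "spleen", "bone_marrow", "tumor")

SAMPLE_SOURCES <- c("spect", "blood_counter")

#' Timed activity-concentration samples
#'
#' Builds a validated data frame of activity-concentration measurements,
#' one row per sample: the organ (or blood) the measurement refers to,
#' the time post-injection in hours, the concentration in MBq/kg, the
#' treatment cycle, and the measurement source (SPECT quantification or
#' well gamma-counter for blood).
#'
#' @param organ Character vector of organ labels (see [SAMPLE_ORGANS]).
#' @param time_h Time post-injection, hours; strictly positive.
#' @param conc Activity concentration, MBq/kg; non-negative.
#' @param cycle Treatment cycle number, positive integer (default 1).
#' @param source `"spect"` or `"blood_counter"`; defaults to
#'   `"blood_counter"` for blood rows and `"spect"` otherwise.
#' @return A `data.frame` of class `timed_samples` with columns `organ`,
#'   `time_h`, `conc`, `cycle`, `source`.
#' @examples
#' timed_samples("kidneys", c(18, 25, 168), c(250, 230, 60))
#' @export
timed_samples <- function(organ, time_h, conc, cycle = 1L, source = NULL) {
  n <- max(length(organ), length(time_h), length(conc), length(cycle))
  organ <- rep_len(as.character(organ), n)
  time_h <- rep_len(as.numeric(time_h), n)
  conc <- rep_len(as.numeric(conc), n)
  cycle <- rep_len(as.integer(cycle), n)
  if (is.null(source)) {
    source <- ifelse(organ == "blood", "blood_counter", "spect")
  } else {
    source <- rep_len(as.character(source), n)
  }
  out <- data.frame(organ = organ, time_h = time_h, conc = conc,
                    cycle = cycle, source = source,
                    stringsAsFactors = FALSE)
  validate_timed_samples(out)
}

validate_timed_samples <- function(x) {
  bad <- setdiff(unique(x$organ), SAMPLE_ORGANS)
  if (length(bad) > 0) {
    abort_prrt(sprintf("unknown organ label(s): %s", paste(bad, collapse = ", ")),
               "prrtdose_domain_error")
  }
  if (any(!is.finite(x$time_h)) || any(x$time_h <= 0)) {
    abort_prrt("all `time_h` must be finite and > 0", "prrtdose_domain_error")
  }
  if (any(!is.finite(x$conc)) || any(x$conc < 0)) {
    abort_prrt("all `conc` must be finite and >= 0", "prrtdose_domain_error")
  }
  if (any(is.na(x$cycle)) || any(x$cycle < 1L)) {
    abort_prrt("all `cycle` must be integers >= 1", "prrtdose_domain_error")
  }
  bad_src <- setdiff(unique(x$source), SAMPLE_SOURCES)
  if (length(bad_src) > 0) {
    abort_prrt(sprintf("unknown source(s): %s", paste(bad_src, collapse = ", ")),
               "prrtdose_domain_error")
  }
  class(x) <- unique(c("timed_samples", class(x)))
  x
}
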