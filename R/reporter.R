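#' Normalize reporter-gene signal by nuclei count
#'
#' Reporter plates are tabular: each well carries a raw luminescence
#' signal and a nuclei count from a single low-magnification image of
#' the nuclear stain. The response is normalized per cell
#' (`raw_signal / nuclei_count`); zero-nuclei wells are flagged
#' cytotoxic and excluded from normalization.
#'
#' @param wells data.frame with at least `raw_signal` and `nuclei_count`
#'   columns.
#' @return `wells` with `normalized_signal` (NA for zero-nuclei wells)
#'   and `cytotoxic_flag` columns.
#' @export
normalize_reporter <- function(wells) {
  if (!all(c("raw_signal", "nuclei_count") %in% names(wells)))
    stop("wells need raw_signal and nuclei_count columns", call. = FALSE)
  if (any(wells$raw_signal < 0, na.rm = TRUE) ||
      any(wells$nuclei_count < 0, na.rm = TRUE))
    stop("raw_signal and nuclei_count must be >= 0", call. = FALSE)
  if (all(wells$nuclei_count == 0))
    stop("all wells have zero nuclei; no viable wells in dataset",
         call. = FALSE)
  wells$cytotoxic_flag <- wells$nuclei_count == 0
  wells$normalized_signal <- ifelse(wells$cytotoxic_flag, NA_real_,
                                    wells$raw_signal / wells$nuclei_count)
  wells
}

#' Express activity as percent of the reference maximum
#'
#' Maps normalized sample responses onto the reference compound's fitted
#' 4PL curve: `100 * (x - bottom) / (top - bottom)` with bottom/top from
#' the reference fit, so the reference top dose reads 100% and baseline
#' 0%.
#'
#' @param values numeric vector of normalized sample responses.
#' @param reference_fit converged, non-degenerate `fourpl_fit` of the
#'   reference dose series.
#' @return numeric vector of percent activities.
#' @export
percent_of_max <- function(values, reference_fit) {
  stopifnot(inherits(reference_fit, "fourpl_fit"))
  if (reference_fit$degenerate || !reference_fit$converged ||
      reference_fit$top <= reference_fit$bottom)
    stop("reference fit is degenerate; cannot express percent of max",
         call. = FALSE)
  100 * (values - reference_fit$bottom) /
    (reference_fit$top - reference_fit$bottom)
}

#' Per-sample reporter activity across experiments
#'
#' For each experiment, fits the reference series, converts the sample's
#' mean normalized response at its highest noncytotoxic dose to percent
#' of the reference maximum, and reports the median across experiments.
#'
#' @param experiments list; each element is a list with `reference`
#'   (data.frame dose, value of the reference series) and `sample`
#'   (numeric vector: the sample's normalized responses at the dose to
#'   report).
#' @return list: `median_percent`, `per_experiment` numeric vector.
#' @export
reporter_activity <- function(experiments) {
  per <- vapply(experiments, function(ex) {
    fit <- fit_4pl(ex$reference$dose, ex$reference$value)
    stats::median(percent_of_max(ex$sample, fit))
  }, numeric(1))
  list(median_percent = stats::median(per), per_experiment = per)
}
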