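#' Ground-truth effect model for the synthetic screen
#'
#' Describes how a treatment shifts the simulated cell population: the
#' fraction of cells that differentiate into adipocytes follows a Hill
#' curve in dose, and per-adipocyte droplet load grows with dose
#' (`maturity_boost`) so that high doses also produce mature adipocytes
#' (summed droplet area >= 1000 px), mirroring the dose-dependent
#' response of the real assay.
#'
#' @param ec50 dose of half-maximal differentiation (same unit as the
#'   doses it is used with). Default 0.75 mg plastic/well, mid-range of
#'   the tested 0.1875-3 series.
#' @param hill Hill slope (> 0), default 1.5.
#' @param base_frac adipocyte fraction at dose 0 (spontaneous
#'   differentiation under 6.25 nM dexamethasone alone), default 0.05.
#' @param max_frac adipocyte fraction at saturating dose, default 0.6.
#' @param droplet_count_mean mean droplets per adipocyte at dose 0
#'   (Poisson, zero-truncated so every adipocyte keeps >= 1 droplet),
#'   default 8.
#' @param droplet_area_log_mean,droplet_area_log_sd log-space parameters
#'   of the droplet pixel-area distribution. Defaults give a median area
#'   of 125 px so that 8 average droplets sum to 1000 px, the mature-
#'   adipocyte threshold.
#' @param intensity_per_area mean droplet peak intensity (a.u.),
#'   default 6000 on the 16-bit scale.
#' @param maturity_boost dose-dependent relative increase of droplet
#'   load: the expected per-adipocyte droplet count is
#'   `droplet_count_mean * (1 + maturity_boost * h(dose))` where `h` is
#'   the same Hill fraction as the differentiation curve. Default 1
#'   (roughly doubles per-cell lipid area at saturation, as the
#'   reference compound does).
#' @return validated `effect_model` object.
#' @export
effect_model <- function(ec50 = 0.75, hill = 1.5, base_frac = 0.05,
                         max_frac = 0.6, droplet_count_mean = 8,
                         droplet_area_log_mean = log(125),
                         droplet_area_log_sd = 0.5,
                         intensity_per_area = 6000,
                         maturity_boost = 1) {
  stopifnot_scalar_number(ec50, "ec50", positive = TRUE)
  stopifnot_scalar_number(hill, "hill", positive = TRUE)
  if (base_frac < 0 || max_frac > 1 || base_frac > max_frac)
    stop("need 0 <= base_frac <= max_frac <= 1", call. = FALSE)
  if (maturity_boost < 0) stop("maturity_boost must be >= 0", call. = FALSE)
  structure(list(ec50 = ec50, hill = hill, base_frac = base_frac,
                 max_frac = max_frac, droplet_count_mean = droplet_count_mean,
                 droplet_area_log_mean = droplet_area_log_mean,
                 droplet_area_log_sd = droplet_area_log_sd,
                 intensity_per_area = intensity_per_area,
                 maturity_boost = maturity_boost),
            class = "effect_model")
}

#' Hill fraction and expected adipocyte fraction at a dose
#'
#' `hill_fraction()` is `dose^h / (dose^h + ec50^h)` (0 at dose 0);
#' `adipocyte_fraction()` is
#' `base_frac + (max_frac - base_frac) * hill_fraction(dose)`.
#'
#' @param model an [effect_model()].
#' @param dose numeric vector of doses (>= 0).
#' @return numeric vector of fractions.
#' @export
adipocyte_fraction <- function(model, dose) {
  stopifnot(inherits(model, "effect_model"))
  model$base_frac + (model$max_frac - model$base_frac) *
    hill_fraction(dose, model$ec50, model$hill)
}

#' @rdname adipocyte_fraction
#' @param ec50,hill Hill parameters.
#' @export
hill_fraction <- function(dose, ec50, hill) {
  ifelse(dose <= 0, 0, dose^hill / (dose^hill + ec50^hill))
}
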