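#' Pool negative and vehicle controls
#'
#' Compares the two control groups with Welch's unequal-variance t test
#' and pools them when they do not differ significantly (p >= alpha);
#' otherwise emits a warning and returns the vehicle controls alone.
#' The statistic is computed in closed form so that identical constant
#' groups give t = 0, p = 1 instead of an error.
#'
#' @param negative,vehicle numeric vectors of control well values
#'   (>= 2 each).
#' @param alpha significance level for the comparison (default 0.05).
#' @return list of class `control_pool`: `values` (the pooled or
#'   vehicle-only vector), `pooled` (logical), `p_value`, `t`, `df`.
#' @export
pool_controls <- function(negative, vehicle, alpha = 0.05) {
  if (length(negative) < 2 || length(vehicle) < 2)
    stop("need >= 2 values in each control group", call. = FALSE)
  m1 <- mean(negative); m2 <- mean(vehicle)
  v1 <- stats::var(negative); v2 <- stats::var(vehicle)
  n1 <- length(negative); n2 <- length(vehicle)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    t_stat <- 0; df <- n1 + n2 - 2
    p <- if (m1 == m2) 1 else 0
    if (m1 != m2) t_stat <- Inf
  } else {
    t_stat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  pooled <- p >= alpha
  if (!pooled)
    warning(sprintf(
      "negative and vehicle controls differ (Welch p = %.3g < %.2g); using vehicle controls only",
      p, alpha), call. = FALSE)
  structure(list(values = if (pooled) c(negative, vehicle) else vehicle,
                 pooled = pooled, p_value = p, t = t_stat, df = df),
            class = "control_pool")
}

#' Limit of detection from pooled controls
#'
#' LOD = control mean + 3 x control SD (sample SD, n-1 denominator), the
#' z = 3 threshold, computed per endpoint and experiment. All-identical
#' controls give SD 0 and are flagged degenerate.
#'
#' @param controls numeric vector of pooled control values (>= 3), or a
#'   [pool_controls()] result.
#' @param endpoint endpoint name carried into the result.
#' @param experiment_id optional experiment identifier.
#' @return list of class `lod_result`: endpoint, experiment_id, n,
#'   control_mean, control_sd, lod_threshold, degenerate.
#' @export
compute_lod <- function(controls, endpoint = NA_character_,
                        experiment_id = NA_character_) {
  if (inherits(controls, "control_pool")) controls <- controls$values
  if (length(controls) < 3)
    stop("need >= 3 pooled control values for an LOD", call. = FALSE)
  m <- mean(controls); s <- stats::sd(controls)
  structure(list(endpoint = endpoint, experiment_id = experiment_id,
                 n = length(controls), control_mean = m, control_sd = s,
                 lod_threshold = m + 3 * s, degenerate = (s == 0)),
            class = "lod_result")
}

#' Cytotoxicity gate and highest noncytotoxic concentration
#'
#' A dose is cytotoxic when its mean nuclei count is more than 20% below
#' the vehicle-control mean (strict: exactly 20% lower is not
#' cytotoxic). The HNC is the highest tested dose that is noncytotoxic
#' at itself and every lower dose; if the lowest dose is already
#' cytotoxic the HNC is NA.
#'
#' @param nuclei data.frame with `dose` and `value` (nuclei count)
#'   columns, replicate wells as rows.
#' @param vehicle numeric vector of vehicle-control nuclei counts.
#' @param threshold_frac fractional loss defining cytotoxicity
#'   (default 0.2).
#' @return list of class `cytotox_result`: `hnc` (dose or NA), `at_max`
#'   (TRUE when hnc is the highest tested dose), `by_dose` data.frame
#'   (dose, mean, cytotoxic).
#' @export
assess_cytotoxicity <- function(nuclei, vehicle, threshold_frac = 0.2) {
  veh_mean <- mean(vehicle)
  if (!is.finite(veh_mean) || veh_mean <= 0)
    stop("vehicle mean must be positive", call. = FALSE)
  doses <- sort(unique(nuclei$dose))
  means <- vapply(doses, function(d) mean(nuclei$value[nuclei$dose == d]),
                  numeric(1))
  cyto <- means < (1 - threshold_frac) * veh_mean
  hnc <- NA_real_
  for (i in seq_along(doses)) {
    if (cyto[i]) break
    hnc <- doses[i]
  }
  structure(list(hnc = hnc, at_max = isTRUE(hnc == max(doses)),
                 by_dose = data.frame(dose = doses, mean = means,
                                      cytotoxic = cyto)),
            class = "cytotox_result")
}

# profile RSS for fixed (ec50, hill): bottom/top solved by linear LS
profile_4pl <- function(dose, value, ec50, hill) {
  w <- hill_fraction(dose, ec50, hill)
  X <- cbind(1 - w, w)
  fit <- tryCatch(stats::lm.fit(X, value), error = function(e) NULL)
  if (is.null(fit)) return(list(rss = Inf))
  list(rss = sum(fit$residuals^2), bottom = fit$coefficients[1],
       top = fit$coefficients[2])
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Model: `y = bottom + (top - bottom) * d^h / (d^h + ec50^h)`.
#' Initialization is a profile grid search over (ec50, hill) with
#' bottom/top solved exactly by linear least squares at each grid point;
#' the best start is refined by [stats::nls()] (port algorithm) in a
#' log-ec50 parameterization that admits negative slopes. The returned
#' fit is canonicalized to `top >= bottom` with `hill > 0` (a decreasing
#' curve folds the slope sign into swapped asymptotes). Flat series are
#' returned as exact degenerate fits.
#'
#' @param dose,value numeric vectors (replicates as repeated doses);
#'   doses must be positive.
#' @param hill_grid,n_ec50_grid initialization grid.
#' @return list of class `fourpl_fit`: bottom, top, ec50, hill, rss,
#'   converged, degenerate, n.
#' @export
fit_4pl <- function(dose, value, hill_grid = c(0.5, 1, 2, 4),
                    n_ec50_grid = 8) {
  if (length(dose) != length(value)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(dose) & is.finite(value)
  dose <- dose[ok]; value <- value[ok]
  if (any(dose <= 0)) stop("doses must be positive", call. = FALSE)
  if (length(unique(dose)) < 2)
    stop("need >= 2 dose levels to fit", call. = FALSE)
  mk <- function(bottom, top, ec50, hill, rss, converged, degenerate)
    structure(list(bottom = unname(bottom), top = unname(top),
                   ec50 = unname(ec50), hill = unname(hill),
                   rss = unname(rss), converged = converged,
                   degenerate = degenerate, n = length(value)),
              class = "fourpl_fit")
  if (stats::sd(value) == 0)
    return(mk(value[1], value[1], stats::median(dose), 1, 0, TRUE, TRUE))
  ec_grid <- exp(seq(log(min(dose)), log(max(dose)), length.out = n_ec50_grid))
  # the linear bottom/top solve is unconstrained, so a decreasing series
  # simply yields bottom > top at positive hill; orientation is fixed by
  # the canonicalization below
  best <- list(rss = Inf)
  for (e in ec_grid) for (h in hill_grid) {
    pr <- profile_4pl(dose, value, e, h)
    if (pr$rss < best$rss) best <- c(pr, list(ec50 = e, hill = h))
  }
  df <- data.frame(d = dose, y = value, ld = log(dose))
  start <- list(b = best$bottom, t = best$top, lec = log(best$ec50),
                h = best$hill)
  fit <- tryCatch(
    stats::nls(y ~ b + (t - b) / (1 + exp(h * (lec - ld))), data = df,
               start = start, algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    bottom <- cf[["b"]]; top <- cf[["t"]]
    ec50 <- exp(cf[["lec"]]); hill <- cf[["h"]]
    rss <- sum(stats::resid(fit)^2)
    converged <- TRUE
  } else {
    bottom <- best$bottom; top <- best$top
    ec50 <- best$ec50; hill <- best$hill
    rss <- best$rss
    converged <- FALSE
  }
  # canonical orientation: bottom <= top, slope sign folded into hill
  # (a decreasing curve has hill < 0 after canonicalization)
  if (bottom > top) { tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill }
  degenerate <- !is.finite(top - bottom) ||
    abs(top - bottom) < 1e-8 * max(1, abs(top), abs(bottom))
  mk(bottom, top, ec50, hill, rss, converged, degenerate)
}

#' Predicted response of a 4PL fit
#'
#' @param object a `fourpl_fit`.
#' @param dose doses at which to evaluate.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.fourpl_fit <- function(object, dose, ...) {
  object$bottom + (object$top - object$bottom) *
    hill_fraction(dose, object$ec50, object$hill)
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<4PL fit: bottom %.4g, top %.4g, ec50 %.4g, hill %.3g, rss %.4g%s%s>\n",
    x$bottom, x$top, x$ec50, x$hill, x$rss,
    if (x$converged) "" else ", NOT converged",
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Diagnostic dose-response plot
#'
#' @param x a `fourpl_fit`.
#' @param dose,value the data that were fitted.
#' @param main plot title.
#' @param ... passed to [plot()].
#' @export
plot.fourpl_fit <- function(x, dose = NULL, value = NULL, main = "4PL fit",
                            ...) {
  if (is.null(dose)) dose <- x$ec50 * 2^seq(-4, 4)
  grid <- exp(seq(log(min(dose)), log(max(dose)), length.out = 100))
  plot(dose, if (is.null(value)) predict(x, dose) else value, log = "x",
       xlab = "dose", ylab = "response", main = main, ...)
  graphics::lines(grid, predict(x, grid), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Interpolate an effect concentration from a 4PL fit
#'
#' EC_f is the dose producing `f`% of the fitted span above bottom:
#' `ec50 * (f / (100 - f))^(1 / hill)` — the closed-form inverse of the
#' 4PL curve at response `bottom + f/100 * (top - bottom)`.
#'
#' @param fit a `fourpl_fit`.
#' @param level percent effect in (0, 100); 50 returns ec50 exactly.
#' @return dose, or NA for degenerate/unconverged fits.
#' @export
interpolate_ec <- function(fit, level) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (level <= 0 || level >= 100)
    stop("level must be in (0, 100)", call. = FALSE)
  if (fit$degenerate || !fit$converged || fit$top <= fit$bottom ||
      fit$hill <= 0)
    return(NA_real_)
  fit$ec50 * (level / (100 - level))^(1 / fit$hill)
}

#' Call adipogenic activity for one sample in one experiment
#'
#' For each endpoint the sample is active when the mean response at any
#' noncytotoxic dose (dose <= HNC) reaches the endpoint's LOD. The
#' sample is adipogenic when at least two endpoints are active. EC10 and
#' EC20 are interpolated from converged 4PL fits of the active
#' endpoints; interpolated values above the highest tested dose are not
#' reported (no extrapolation).
#'
#' @param series named list mapping endpoint name to a data.frame with
#'   `dose` and `value` columns (replicate wells as rows).
#' @param lods named list mapping endpoint name to [compute_lod()]
#'   results.
#' @param hnc highest noncytotoxic dose ([assess_cytotoxicity()]`$hnc`);
#'   NA means every dose is cytotoxic and nothing can be called active.
#' @param sample_id identifier carried into the call.
#' @param min_active_endpoints endpoints required for an activity call
#'   (default 2).
#' @return list of class `activity_call`: sample_id, hnc, active,
#'   n_active_endpoints, per_endpoint (data.frame: endpoint, active,
#'   max_response, lod_threshold, ec10, ec20), ec10, ec20 (sample-level
#'   medians over active endpoints).
#' @export
call_activity <- function(series, lods, hnc, sample_id = NA_character_,
                          min_active_endpoints = 2L) {
  endpoints <- names(series)
  rows <- list()
  for (ep in endpoints) {
    s <- series[[ep]]
    lod <- lods[[ep]]
    if (is.null(s) || !nrow(s) || is.null(lod)) {
      warning(sprintf("endpoint %s missing for sample %s; skipped (not counted as active)",
                      ep, sample_id), call. = FALSE)
      next
    }
    usable <- if (is.na(hnc)) s[0, ] else s[s$dose <= hnc, , drop = FALSE]
    if (!nrow(usable)) {
      rows[[ep]] <- data.frame(endpoint = ep, active = FALSE,
                               max_response = NA_real_,
                               lod_threshold = lod$lod_threshold,
                               ec10 = NA_real_, ec20 = NA_real_)
      next
    }
    dose_means <- tapply(usable$value, usable$dose, mean)
    max_resp <- max(dose_means)
    act <- max_resp >= lod$lod_threshold
    ec10 <- ec20 <- NA_real_
    if (act && length(unique(s$dose)) >= 2) {
      fit <- tryCatch(fit_4pl(s$dose, s$value), error = function(e) NULL)
      if (!is.null(fit) && fit$converged && !fit$degenerate) {
        max_dose <- max(s$dose)
        e10 <- interpolate_ec(fit, 10)
        e20 <- interpolate_ec(fit, 20)
        if (is.finite(e10) && e10 <= max_dose) ec10 <- e10
        if (is.finite(e20) && e20 <= max_dose) ec20 <- e20
      }
    }
    rows[[ep]] <- data.frame(endpoint = ep, active = act,
                             max_response = max_resp,
                             lod_threshold = lod$lod_threshold,
                             ec10 = ec10, ec20 = ec20)
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(endpoint = character(0), active = logical(0),
               max_response = numeric(0), lod_threshold = numeric(0),
               ec10 = numeric(0), ec20 = numeric(0))
  rownames(per) <- NULL
  n_active <- sum(per$active)
  med_or_na <- function(x) if (any(is.finite(x))) stats::median(x[is.finite(x)]) else NA_real_
  structure(list(sample_id = sample_id, hnc = hnc,
                 active = n_active >= min_active_endpoints,
                 n_active_endpoints = n_active, per_endpoint = per,
                 ec10 = med_or_na(per$ec10[per$active]),
                 ec20 = med_or_na(per$ec20[per$active])),
            class = "activity_call")
}

#' Aggregate activity calls across independent experiments
#'
#' A sample is called adipogenic overall when the two-endpoint rule
#' holds in at least `min_experiments` (default 2) of the independent
#' experiments.
#'
#' @param calls list of `activity_call`s for the same sample.
#' @param min_experiments experiments required (default 2 of >= 3).
#' @return list: sample_id, active, n_active_experiments, n_experiments.
#' @export
aggregate_calls <- function(calls, min_experiments = 2L) {
  act <- vapply(calls, function(x) isTRUE(x$active), logical(1))
  list(sample_id = calls[[1]]$sample_id,
       active = sum(act) >= min_experiments,
       n_active_experiments = sum(act),
       n_experiments = length(calls))
}
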