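# Tabular screen simulator and end-to-end analysis: the scaled-down
# planted-truth analog of the full imaging screen. Well-level endpoint
# values are drawn directly from the same effect/noise model the image
# generator encodes, so the plate-statistics path can be validated on a
# full 34-sample, multi-experiment screen within desk-scale runtime;
# the imaging path itself is validated against rendered fields.

#' Default endpoint baselines for the tabular screen simulator
#'
#' Per-well control means for the six endpoints (sums over the nine
#' fields of a well at the default imaging configuration) and the
#' common well-to-well coefficient of variation.
#' @return named list.
#' @export
screen_baselines <- function() {
  list(means = c(nuclei_count = 720, droplet_count = 400,
                 total_area = 50000, total_intensity = 1.5e8,
                 n_adipocytes = 36, n_mature = 7),
       cv = 0.05)
}

#' Simulate a planted-truth screening campaign
#'
#' Generates well-level endpoint data for `n_experiments` independent
#' experiments of a full screen: every sample in five 1:2 dilutions from
#' 3 mg plastic/well with four replicates, plus vehicle and negative
#' control wells. Planted active samples receive a Hill-shaped increase
#' on all adipogenic endpoints scaled so the response at the sample's
#' highest noncytotoxic dose equals `effect_sd` control standard
#' deviations; planted cytotoxic samples lose half their nuclei at
#' doses above their planted HNC. All noise is Gaussian with the
#' baseline CV.
#'
#' @param samples character vector of sample ids (default the 34
#'   published product labels).
#' @param active character vector of planted active samples (default:
#'   eleven samples mirroring the published pattern — most PVC/PUR
#'   products plus single PP/PS/LDPE products).
#' @param cytotoxic named numeric vector: planted HNC (mg/well) per
#'   cytotoxic sample; doses above it are cytotoxic. Default mirrors the
#'   published HNCs (one sample at 1.5, two at 0.75).
#' @param effect_sd planted effect size at the HNC, in control SDs
#'   (default 8).
#' @param n_experiments independent experiments (default 3).
#' @param top_dose,n_concentrations,dilution_factor,replicates dose
#'   design (defaults 3, 5, 1:2, 4).
#' @param n_vehicle,n_negative control wells per experiment.
#' @param ec50,hill shape of the planted dose-response (defaults 0.75
#'   mg/well, 1.5).
#' @param baselines [screen_baselines()]-style list.
#' @param seed integer seed.
#' @return list: `wells` (long data.frame: experiment, treatment,
#'   sample_id, dose, one column per endpoint), `planted` (list with
#'   `active`, `hnc` per sample), `endpoints` (endpoint names).
#' @export
simulate_screen <- function(samples = table1_counts()$sample,
                            active = c("PVC 2", "PVC 3", "PVC 4", "PUR 1",
                                       "PUR 2", "PUR 3", "PUR 4", "PP 2",
                                       "PP 4", "PS 2", "LDPE 4"),
                            cytotoxic = c("PP 4" = 1.5, "PUR 3" = 0.75,
                                          "PUR 4" = 0.75),
                            effect_sd = 8, n_experiments = 3,
                            top_dose = 3, n_concentrations = 5,
                            dilution_factor = 2, replicates = 4,
                            n_vehicle = 4, n_negative = 4,
                            ec50 = 0.75, hill = 1.5,
                            baselines = screen_baselines(), seed = 1L) {
  stopifnot(all(active %in% samples), all(names(cytotoxic) %in% samples))
  doses <- dose_series(top_dose, n_concentrations, dilution_factor)
  eps <- names(baselines$means)
  adipo_eps <- setdiff(eps, "nuclei_count")
  hnc_of <- function(s) {
    if (s %in% names(cytotoxic)) unname(cytotoxic[[s]]) else max(doses)
  }
  planted_hnc <- setNames(vapply(samples, hnc_of, numeric(1)), samples)
  rows <- list()
  with_seed(seed, {
    for (ex in seq_len(n_experiments)) {
      draw <- function(mean_vec) {
        vapply(eps, function(e)
          max(0, rnorm(1, mean_vec[[e]], baselines$cv * baselines$means[[e]])),
          numeric(1))
      }
      add_well <- function(treatment, sample_id, dose, mean_vec) {
        rows[[length(rows) + 1L]] <<- as.data.frame(c(
          list(experiment = ex, treatment = treatment,
               sample_id = sample_id, dose = dose),
          as.list(draw(mean_vec))), stringsAsFactors = FALSE)
      }
      for (k in seq_len(n_vehicle))
        add_well("vehicle", NA_character_, 0, baselines$means)
      for (k in seq_len(n_negative))
        add_well("negative", NA_character_, 0, baselines$means)
      for (s in samples) {
        hnc <- planted_hnc[[s]]
        for (d in doses) {
          mu <- baselines$means
          if (s %in% active) {
            scale <- hill_fraction(d, ec50, hill) /
              hill_fraction(hnc, ec50, hill)
            for (e in adipo_eps)
              mu[[e]] <- mu[[e]] +
                effect_sd * baselines$cv * baselines$means[[e]] * scale
          }
          if (d > hnc) mu[["nuclei_count"]] <- 0.5 * mu[["nuclei_count"]]
          for (k in seq_len(replicates)) add_well("sample", s, d, mu)
        }
      }
    }
  })
  wells <- do.call(rbind, rows)
  rownames(wells) <- NULL
  list(wells = wells,
       planted = list(active = sort(active), hnc = planted_hnc),
       endpoints = eps)
}

#' Analyze a screening campaign end to end
#'
#' Per experiment: pools negative and vehicle controls per endpoint,
#' computes LODs, gates cytotoxicity on nuclei counts to find each
#' sample's HNC, and calls multi-endpoint activity; samples are then
#' called adipogenic overall when active in at least `min_experiments`
#' experiments. The reported HNC is the minimum across experiments (the
#' most conservative noncytotoxic claim).
#'
#' @param screen a [simulate_screen()] result, or a compatible list
#'   with `wells` and `endpoints`.
#' @param calling_endpoints endpoints entering the two-endpoint rule
#'   (default: all adipogenic endpoints, i.e. everything except the
#'   nuclei count, which feeds the cytotoxicity gate).
#' @param min_experiments experiments required for the overall call.
#' @return data.frame, one row per sample: sample_id, active,
#'   n_active_experiments, hnc; attribute `calls` holds the per-
#'   experiment `activity_call`s.
#' @export
analyze_screen <- function(screen, calling_endpoints = NULL,
                           min_experiments = 2L) {
  wells <- screen$wells
  eps <- screen$endpoints
  if (is.null(calling_endpoints))
    calling_endpoints <- setdiff(eps, "nuclei_count")
  samples <- sort(unique(wells$sample_id[wells$treatment == "sample"]))
  experiments <- sort(unique(wells$experiment))
  all_calls <- list()
  hncs <- list()
  for (ex in experiments) {
    w <- wells[wells$experiment == ex, , drop = FALSE]
    veh <- w[w$treatment == "vehicle", , drop = FALSE]
    neg <- w[w$treatment == "negative", , drop = FALSE]
    lods <- list()
    for (e in calling_endpoints) {
      pool <- pool_controls(neg[[e]], veh[[e]])
      lods[[e]] <- compute_lod(pool, endpoint = e, experiment_id = ex)
    }
    for (s in samples) {
      sw <- w[w$treatment == "sample" & w$sample_id == s, , drop = FALSE]
      cyto <- assess_cytotoxicity(
        data.frame(dose = sw$dose, value = sw$nuclei_count),
        veh$nuclei_count)
      series <- lapply(setNames(calling_endpoints, calling_endpoints),
                       function(e) data.frame(dose = sw$dose, value = sw[[e]]))
      call <- call_activity(series, lods, cyto$hnc, sample_id = s)
      all_calls[[s]] <- c(all_calls[[s]], list(call))
      hncs[[s]] <- c(hncs[[s]], cyto$hnc)
    }
  }
  out <- do.call(rbind, lapply(samples, function(s) {
    agg <- aggregate_calls(all_calls[[s]], min_experiments)
    h <- hncs[[s]]
    data.frame(sample_id = s, active = agg$active,
               n_active_experiments = agg$n_active_experiments,
               hnc = if (all(is.na(h))) NA_real_ else min(h, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  attr(out, "calls") <- all_calls
  out
}
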