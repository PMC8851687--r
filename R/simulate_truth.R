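# Ground-truth simulation: cell populations with dose-dependent
# differentiation, placed in fields by minimum-distance rejection
# sampling so that rendered objects can be kept resolvable on demand.

place_points <- function(n, shape, margin, min_dist, max_tries = 200L,
                         existing = NULL) {
  pts <- if (is.null(existing)) matrix(numeric(0), 0, 2) else existing
  n_existing <- nrow(pts)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- c(runif(1, margin, shape[1] - 1 - margin),
             runif(1, margin, shape[2] - 1 - margin))
      if (nrow(pts) == 0 ||
          min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_dist^2) {
        pts <- rbind(pts, p)
        placed <- TRUE
        break
      }
    }
    if (!placed) break # field saturated; caller sees fewer objects
  }
  if (nrow(pts) > n_existing)
    pts[(n_existing + 1):nrow(pts), , drop = FALSE]
  else matrix(numeric(0), 0, 2)
}

#' Simulate the ground truth of a single imaging field
#'
#' Draws a cell population with the requested adipocyte fraction, places
#' nuclei by minimum-distance rejection sampling, and scatters lipid
#' droplets in an annulus around each adipocyte's nucleus. Droplet areas
#' are log-normal; droplet discs are kept inside the field and (when
#' `droplet_min_gap > 0`) pairwise separated so segmentation oracles can
#' demand exact counts.
#'
#' @param n_cells cells to attempt to place.
#' @param adipo_frac probability that a cell is an adipocyte.
#' @param model an [effect_model()] supplying droplet-load parameters.
#' @param dose dose driving the maturity boost (same units as
#'   `model$ec50`).
#' @param config an [imaging_config()].
#' @param seed integer seed.
#' @param cell_min_distance minimum nucleus-centroid separation (px).
#' @param droplet_min_gap minimum gap between droplet disc edges (px).
#' @param droplet_zone annulus width around the nucleus within which
#'   droplets are placed (px).
#' @param field_id list with `well_id` and `field_index`.
#' @return a `field_truth` object: list with `field_id`, `cells`
#'   (data.frame: cell_id, row, col, nucleus_radius, is_adipocyte) and
#'   `droplets` (data.frame: droplet_id, cell_id, row, col, radius,
#'   area, peak_intensity).
#' @export
simulate_field_truth <- function(n_cells, adipo_frac, model = effect_model(),
                                 dose = 0, config = imaging_config(),
                                 seed = 1L, cell_min_distance = 24,
                                 droplet_min_gap = 2, droplet_zone = 18,
                                 field_id = list(well_id = "W1", field_index = 0L)) {
  stopifnot(inherits(model, "effect_model"), inherits(config, "imaging_config"))
  if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  shape <- config$field_shape
  with_seed(seed, {
    r_nuc_max <- 10
    centers <- place_points(n_cells, shape, margin = r_nuc_max + 2,
                            min_dist = cell_min_distance)
    n <- nrow(centers)
    cells <- data.frame(cell_id = seq_len(n),
                        row = centers[, 1], col = centers[, 2],
                        nucleus_radius = pmin(r_nuc_max, pmax(6, rnorm(n, 8, 0.8))),
                        is_adipocyte = as.logical(rbinom(n, 1, adipo_frac)))
    rownames(cells) <- NULL
    h <- hill_fraction(dose, model$ec50, model$hill)
    lambda <- model$droplet_count_mean * (1 + model$maturity_boost * h)
    drops <- list()
    placed <- matrix(numeric(0), 0, 3) # row, col, radius of placed droplets
    did <- 0L
    for (i in seq_len(n)) {
      if (!cells$is_adipocyte[i]) next
      k <- max(1L, rpois(1, lambda))
      areas <- rlnorm(k, model$droplet_area_log_mean, model$droplet_area_log_sd)
      radii <- pmin(12, pmax(1.5, sqrt(areas / pi)))
      for (j in seq_len(k)) {
        r <- radii[j]
        ok <- FALSE
        for (t in 1:60) {
          ang <- runif(1, 0, 2 * pi)
          rad <- runif(1, cells$nucleus_radius[i] + 1, cells$nucleus_radius[i] + droplet_zone)
          p <- c(cells$row[i] + rad * sin(ang), cells$col[i] + rad * cos(ang))
          if (p[1] < r + 1 || p[1] > shape[1] - 2 - r ||
              p[2] < r + 1 || p[2] > shape[2] - 2 - r) next
          if (nrow(placed) > 0 && droplet_min_gap >= 0) {
            gap <- sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) -
              placed[, 3] - r
            if (min(gap) < droplet_min_gap) next
          }
          ok <- TRUE
          break
        }
        if (!ok) next # crowded; droplet dropped from truth
        did <- did + 1L
        placed <- rbind(placed, c(p, r))
        drops[[did]] <- data.frame(
          droplet_id = did, cell_id = cells$cell_id[i],
          row = p[1], col = p[2], radius = r, area = pi * r^2,
          peak_intensity = max(0.2 * model$intensity_per_area,
                               rnorm(1, model$intensity_per_area,
                                     0.1 * model$intensity_per_area)))
      }
    }
    droplets <- if (did > 0) do.call(rbind, drops) else
      data.frame(droplet_id = integer(0), cell_id = integer(0),
                 row = numeric(0), col = numeric(0), radius = numeric(0),
                 area = numeric(0), peak_intensity = numeric(0))
    rownames(droplets) <- NULL
    structure(list(field_id = field_id, cells = cells, droplets = droplets),
              class = "field_truth")
  })
}

#' Simulate ground truth for every field of a plate design
#'
#' Applies an effect model to each well of a [design_plate()] layout:
#' `sample` and `reference` wells differentiate according to the model's
#' Hill curve at the well's dose, `vehicle` and `negative` wells sit at
#' the baseline fraction, `preadipocyte_control` wells contain no
#' adipocytes, and `blank` wells contain no cells.
#'
#' @param design a `plate_design`.
#' @param model an [effect_model()], or a named list of models keyed by
#'   `sample_id` (key `"rosiglitazone"` for reference wells) with an
#'   optional `.default` entry.
#' @param cells_per_field cells per imaged field.
#' @param config an [imaging_config()] (`fields_per_well` is honoured).
#' @param seed screen-level seed; each field derives its own stream.
#' @param wells optional character vector restricting to given well ids.
#' @param ... passed to [simulate_field_truth()].
#' @return list of `field_truth` objects.
#' @export
simulate_truth <- function(design, model, cells_per_field = 80L,
                           config = imaging_config(), seed = 1L,
                           wells = NULL, ...) {
  stopifnot(inherits(design, "plate_design"))
  pick_model <- function(sample_id) {
    if (inherits(model, "effect_model")) return(model)
    model[[sample_id]] %||% model[[".default"]] %||%
      stop("no effect model for sample ", sample_id, call. = FALSE)
  }
  w <- design$wells
  if (!is.null(wells)) w <- w[w$well_id %in% wells, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(w))) {
    trt <- w$treatment[i]
    if (trt == "blank") next
    m <- switch(trt,
      sample = pick_model(w$sample_id[i]),
      reference = pick_model("rosiglitazone"),
      if (inherits(model, "effect_model")) model else
        model[[".default"]] %||% effect_model())
    frac <- switch(trt,
      sample = , reference = adipocyte_fraction(m, w$dose[i]),
      vehicle = , negative = m$base_frac,
      preadipocyte_control = 0)
    dose <- if (trt %in% c("sample", "reference")) w$dose[i] else 0
    for (f in seq_len(config$fields_per_well) - 1L) {
      fid <- list(well_id = w$well_id[i], field_index = f)
      fseed <- child_seed(seed, i * 64L + f)
      out[[length(out) + 1L]] <- simulate_field_truth(
        cells_per_field, frac, model = m, dose = dose, config = config,
        seed = fseed, field_id = fid, ...)
    }
  }
  out
}
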