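# Shared fixtures: small imaging configs and hand-built truth objects.

cfg_small <- function(noise = "none", sd = 600, shape = c(256L, 256L)) {
  imaging_config(field_shape = shape, noise_model = noise,
                 noise_params = list(sd = sd))
}

# hand-built field truth with explicit objects (bypasses the simulator)
manual_truth <- function(cells = NULL, droplets = NULL,
                         well_id = "W1", field_index = 0L) {
  if (is.null(cells))
    cells <- data.frame(cell_id = integer(0), row = numeric(0),
                        col = numeric(0), nucleus_radius = numeric(0),
                        is_adipocyte = logical(0))
  if (is.null(droplets))
    droplets <- data.frame(droplet_id = integer(0), cell_id = integer(0),
                           row = numeric(0), col = numeric(0),
                           radius = numeric(0), area = numeric(0),
                           peak_intensity = numeric(0))
  structure(list(field_id = list(well_id = well_id,
                                 field_index = field_index),
                 cells = cells, droplets = droplets),
            class = "field_truth")
}

manual_cells <- function(rows, cols, radius = 8, adipo = FALSE) {
  n <- length(rows)
  data.frame(cell_id = seq_len(n), row = rows, col = cols,
             nucleus_radius = rep_len(radius, n),
             is_adipocyte = rep_len(adipo, n))
}

manual_droplets <- function(rows, cols, radius = 6, cell_id = 1L,
                            peak = 6000) {
  n <- length(rows)
  data.frame(droplet_id = seq_len(n), cell_id = rep_len(cell_id, n),
             row = rows, col = cols, radius = rep_len(radius, n),
             area = pi * rep_len(radius, n)^2,
             peak_intensity = rep_len(peak, n))
}

# random adipocyte records for brute-force oracles
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    k <- rbinom(n, 1, 0.6)
    area <- ifelse(k == 1, rlnorm(n, log(400), 0.8), 0)
    data.frame(cell_id = seq_len(n), droplet_count = ifelse(k == 1,
               1L + rpois(n, 5), 0L), lipid_area = area,
               avg_intensity = ifelse(k == 1, rnorm(n, 50, 8), NA_real_),
               is_adipocyte = k == 1, is_mature = FALSE,
               norm_intensity = NA_real_)
  })
}
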