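#' Otsu's automatic threshold
#'
#' Classic between-class-variance maximization on the integer histogram.
#' Returns the threshold value `t`; foreground is `img > t`. A constant
#' image returns `Inf` (no foreground) rather than an error.
#'
#' @param img numeric or integer matrix.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(img) {
  v <- as.integer(round(img))
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(Inf)
  counts <- tabulate(v - lo + 1L, nbins = hi - lo + 1L)
  vals <- lo:hi
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * vals)
  mu_t <- mu[length(mu)]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  vals[which.max(sigma_b)]
}

#' Segmentation parameter set
#'
#' Every operator of the imaging module is driven by this declared,
#' tunable parameter list (the published analysis ran in an external
#' pipeline whose settings are not printed; these defaults are this
#' package's documented equivalents).
#'
#' @param smooth_sigma Gaussian smoothing before nuclei thresholding (px).
#' @param threshold_method currently `"otsu"`.
#' @param min_area,max_area nucleus size gate (px).
#' @param declump_min_sep minimum separation of watershed seeds (px);
#'   two distance-transform maxima closer than this are merged.
#' @param min_seed_value minimum distance-transform value for a seed.
#' @param min_snr robustness guard: the effective threshold is at least
#'   `median + min_snr * mad` of the image, suppressing noise-split
#'   foreground on (near-)blank fields.
#' @param droplet_smooth_sigma smoothing before droplet thresholding.
#' @param min_droplet_area droplet size gate (px), default 9 to suppress
#'   single-pixel noise.
#' @param droplet_declump whether to watershed-declump droplets.
#' @param max_cell_radius maximum geodesic expansion of a cell region
#'   from its nucleus (px).
#' @param max_assign_distance maximum distance from a cell region within
#'   which a non-overlapping droplet is still assigned to it (px).
#' @param background_subtract subtract the per-image median background
#'   from droplet intensities before integration.
#' @param keep_border_objects keep objects touching the field border
#'   (default TRUE: endpoints are per image and exclusion would bias
#'   proliferation).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma = 1, threshold_method = "otsu",
                                min_area = 20, max_area = 500,
                                declump_min_sep = 8, min_seed_value = 1.5,
                                min_snr = 3, droplet_smooth_sigma = 1,
                                min_droplet_area = 9, droplet_declump = FALSE,
                                max_cell_radius = 40, max_assign_distance = 30,
                                background_subtract = TRUE,
                                keep_border_objects = TRUE) {
  structure(as.list(environment()), class = "segmentation_params")
}

# threshold with robust background guard; returns effective threshold
effective_threshold <- function(img, min_snr) {
  th <- otsu_threshold(img)
  med <- stats::median(img)
  guard <- med + min_snr * stats::mad(img)
  max(th, guard)
}

# label mask, optionally splitting touching objects by seeded growing
# from distance-transform maxima
label_and_declump <- function(mask, declump, min_sep, min_seed_value) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (!declump) return(.cc_label(mask, 8L))
  d <- .chamfer_dist(mask)
  mx <- .local_maxima(d, min_sep, min_seed_value)
  if (nrow(mx) == 0) return(.cc_label(mask, 8L))
  seeds <- matrix(0L, nrow(mask), ncol(mask))
  seeds[mx + 1L] <- seq_len(nrow(mx))
  .grow_seeds(seeds, mask, Inf)
}

# per-label measurements on a label map; weights for centroids
measure_labels <- function(labels, weight) {
  idx <- which(labels > 0)
  if (!length(idx))
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      area = integer(0), integrated = numeric(0)))
  lab <- labels[idx]
  nr <- nrow(labels)
  rows0 <- (idx - 1L) %% nr        # 0-based row
  cols0 <- (idx - 1L) %/% nr       # 0-based col
  w <- pmax(weight[idx], 1e-9)
  area <- as.vector(rowsum(rep(1L, length(idx)), lab))
  wsum <- as.vector(rowsum(w, lab))
  wr <- as.vector(rowsum(w * rows0, lab)) / wsum
  wc <- as.vector(rowsum(w * cols0, lab)) / wsum
  integ <- as.vector(rowsum(weight[idx], lab))
  data.frame(label = sort(unique(lab)), row = wr, col = wc,
             area = area, integrated = integ)
}

#' Segment nuclei in the nuclear-stain channel
#'
#' Smoothing, global automatic (Otsu) thresholding with a robust
#' background guard, distance-transform watershed declumping of touching
#' nuclei, and a `[min_area, max_area]` size gate. Centroids are
#' intensity weighted (0-based pixel coordinates).
#'
#' @param nuclei_channel integer matrix (nuclear channel).
#' @param params a [segmentation_params()].
#' @return list of class `nuclei_seg`: `table` (nucleus_id, row, col,
#'   area), `labels` (integer label map), `threshold`.
#' @export
segment_nuclei <- function(nuclei_channel, params = segmentation_params()) {
  stopifnot(is.matrix(nuclei_channel))
  sm <- gaussian_blur(nuclei_channel, params$smooth_sigma, "constant")
  th <- effective_threshold(sm, params$min_snr)
  mask <- sm > th
  labels <- label_and_declump(mask, TRUE, params$declump_min_sep,
                              params$min_seed_value)
  weight <- pmax(sm - stats::median(sm), 0)
  tab <- measure_labels(labels, weight)
  keep <- tab$area >= params$min_area & tab$area <= params$max_area
  tab <- tab[keep, , drop = FALSE]
  labels[!(labels %in% tab$label)] <- 0L
  # relabel consecutively
  if (nrow(tab)) {
    remap <- integer(max(tab$label)); remap[tab$label] <- seq_len(nrow(tab))
    labels[labels > 0] <- remap[labels[labels > 0]]
    tab$label <- seq_len(nrow(tab))
  }
  table <- data.frame(nucleus_id = tab$label, row = tab$row, col = tab$col,
                      area = tab$area)
  structure(list(table = table, labels = labels, threshold = th),
            class = "nuclei_seg")
}

#' Delineate cell regions by seeded growing from nuclei
#'
#' Each nucleus grows into a cell region by multi-source geodesic
#' expansion, bounded by `max_cell_radius`; equidistant pixels go to the
#' lowest cell id, so regions are deterministic and pairwise disjoint,
#' and every nucleus yields exactly one cell containing it. Pixels
#' beyond the radius stay background.
#'
#' @param nuclei a `nuclei_seg` from [segment_nuclei()].
#' @param lipid_channel lipid channel matrix (fixes the field geometry;
#'   the growth region is the whole field within the radius bound).
#' @param params a [segmentation_params()].
#' @return list of class `cell_map`: `labels` (cell label map, cell_id =
#'   nucleus_id) and `table` (cell_id, nucleus_id, area).
#' @export
delineate_cells <- function(nuclei, lipid_channel,
                            params = segmentation_params()) {
  stopifnot(inherits(nuclei, "nuclei_seg"))
  if (!all(dim(nuclei$labels) == dim(lipid_channel)))
    stop("channel shapes differ", call. = FALSE)
  allowed <- matrix(TRUE, nrow(lipid_channel), ncol(lipid_channel))
  labels <- .grow_seeds(nuclei$labels, allowed, params$max_cell_radius)
  ids <- nuclei$table$nucleus_id
  area <- tabulate(labels[labels > 0], nbins = max(ids, 0L))
  table <- data.frame(cell_id = ids, nucleus_id = ids,
                      area = if (length(ids)) area[ids] else integer(0))
  structure(list(labels = labels, table = table), class = "cell_map")
}

#' Detect lipid droplets in the lipid-stain channel
#'
#' Background-corrected threshold segmentation (Otsu with robust guard)
#' with optional watershed declumping; per-droplet pixel area and
#' integrated, median-background-subtracted intensity. Droplets below
#' `min_droplet_area` are discarded.
#'
#' @param lipid_channel integer matrix.
#' @param params a [segmentation_params()].
#' @return list of class `droplet_seg`: `table` (droplet_id, row, col,
#'   area, integrated_intensity), `labels`, `background`, `threshold`.
#' @export
detect_droplets <- function(lipid_channel, params = segmentation_params()) {
  stopifnot(is.matrix(lipid_channel))
  sm <- gaussian_blur(lipid_channel, params$droplet_smooth_sigma, "constant")
  th <- effective_threshold(sm, params$min_snr)
  mask <- sm > th
  labels <- label_and_declump(mask, params$droplet_declump,
                              params$declump_min_sep, params$min_seed_value)
  bg <- stats::median(lipid_channel)
  weight <- if (params$background_subtract) lipid_channel - bg else
    lipid_channel + 0
  tab <- measure_labels(labels, weight)
  keep <- tab$area >= params$min_droplet_area
  tab <- tab[keep, , drop = FALSE]
  labels[!(labels %in% tab$label)] <- 0L
  if (nrow(tab)) {
    remap <- integer(max(tab$label)); remap[tab$label] <- seq_len(nrow(tab))
    labels[labels > 0] <- remap[labels[labels > 0]]
    tab$label <- seq_len(nrow(tab))
  }
  table <- data.frame(droplet_id = tab$label, row = tab$row, col = tab$col,
                      area = tab$area, integrated_intensity = tab$integrated)
  structure(list(table = table, labels = labels, background = bg,
                 threshold = th), class = "droplet_seg")
}

#' Assign droplets to cells
#'
#' Each droplet goes to the cell with maximal pixel overlap; droplets
#' with no overlap are assigned to the nearest cell region within
#' `max_assign_distance`, and stay unassigned (`cell_id = NA`) beyond
#' that. Ties break to the lowest cell id. Unassigned droplets remain in
#' the table — image-level endpoints count them.
#'
#' @param droplets a `droplet_seg`.
#' @param cells a `cell_map`.
#' @param params a [segmentation_params()].
#' @return the droplet table with a `cell_id` column.
#' @export
assign_droplets <- function(droplets, cells, params = segmentation_params()) {
  stopifnot(inherits(droplets, "droplet_seg"), inherits(cells, "cell_map"))
  if (!all(dim(droplets$labels) == dim(cells$labels)))
    stop("droplet and cell maps come from different fields", call. = FALSE)
  tab <- droplets$table
  tab$cell_id <- rep(NA_integer_, nrow(tab))
  if (!nrow(tab)) return(tab)
  # extension map: every pixel within max_assign_distance of a cell
  # region carries that cell's id (nearest region, lowest id on ties)
  allowed <- matrix(TRUE, nrow(cells$labels), ncol(cells$labels))
  extended <- .grow_seeds(cells$labels, allowed, params$max_assign_distance)
  idx <- which(droplets$labels > 0)
  dlab <- droplets$labels[idx]
  clab <- cells$labels[idx]
  for (i in seq_len(nrow(tab))) {
    mine <- clab[dlab == tab$droplet_id[i]]
    mine <- mine[mine > 0]
    if (length(mine)) {
      counts <- table(mine)
      best <- as.integer(names(counts)[counts == max(counts)])
      tab$cell_id[i] <- min(best)
    } else {
      px <- cbind(round(tab$row[i]) + 1L, round(tab$col[i]) + 1L)
      lab <- extended[px]
      if (lab > 0) tab$cell_id[i] <- lab
    }
  }
  tab
}

#' Bundle segmentation results for one field
#'
#' @param images a `field_images` (or list with `nuclei` and `lipid`
#'   matrices and a `field_id`).
#' @param params a [segmentation_params()].
#' @return an `object_tables` object: `nuclei`, `cells`, `droplets`
#'   data.frames (droplets carry `cell_id`), the two label maps, and the
#'   `field_id`.
#' @export
segment_field <- function(images, params = segmentation_params()) {
  nuc <- segment_nuclei(images$nuclei, params)
  cm <- delineate_cells(nuc, images$lipid, params)
  dr <- detect_droplets(images$lipid, params)
  drops <- assign_droplets(dr, cm, params)
  structure(list(nuclei = nuc$table, cells = cm$table, droplets = drops,
                 cell_labels = cm$labels, droplet_labels = dr$labels,
                 field_id = images$field_id %||% NULL),
            class = "object_tables")
}

#' Per-image endpoints
#'
#' The four imaging endpoints: proliferation as nuclei count, and
#' adipogenesis as the number of lipid droplets, the total droplet area,
#' and the total (background-subtracted) droplet intensity per image.
#' Sums are taken over the droplet table exactly as measured (unassigned
#' droplets included; endpoints are per image, not per cell).
#'
#' @param tables an `object_tables` from [segment_field()] (or a list
#'   with `nuclei` and `droplets` data.frames).
#' @return one-row data.frame: nuclei_count, droplet_count, total_area,
#'   total_intensity.
#' @export
compute_image_endpoints <- function(tables) {
  data.frame(nuclei_count = nrow(tables$nuclei),
             droplet_count = nrow(tables$droplets),
             total_area = sum(tables$droplets$area),
             total_intensity = sum(tables$droplets$integrated_intensity))
}
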