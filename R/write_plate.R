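#' Write a simulated plate to disk
#'
#' Writes one TIFF per field and channel (file pattern
#' `{plate}_{well}_{field}_{channel}.tiff`), the ground-truth cell and
#' droplet tables as CSV, the plate design as JSON, and a manifest JSON
#' listing every file with its MD5 checksum. Coordinates in the truth
#' CSVs are 0-based (row, col) pixels; areas are pixel counts;
#' intensities arbitrary units (documented in the manifest).
#'
#' @param design a `plate_design`.
#' @param truths list of `field_truth` objects.
#' @param images list of `field_images` objects parallel to `truths`.
#' @param out_dir output directory (created if missing).
#' @return path to the manifest JSON, invisibly.
#' @export
write_plate <- function(design, truths, images, out_dir) {
  if (length(truths) != length(images))
    stop("truths and images must be parallel lists", call. = FALSE)
  for (i in seq_along(truths))
    if (!identical(truths[[i]]$field_id, images[[i]]$field_id))
      stop("field_id mismatch between truths and images at position ", i,
           call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- character(0)
  add_file <- function(p) files[length(files) + 1L] <<- p
  n_images <- 0L
  cell_rows <- list(); drop_rows <- list()
  for (i in seq_along(truths)) {
    tr <- truths[[i]]; im <- images[[i]]
    stem <- sprintf("%s_%s_%d", design$plate_id, tr$field_id$well_id,
                    tr$field_id$field_index)
    for (ch in c("nuclei", "lipid")) {
      p <- file.path(out_dir, sprintf("%s_%s.tiff", stem, ch))
      write_tiff(p, im[[ch]], bit_depth = im$config$bit_depth)
      add_file(p)
      n_images <- n_images + 1L
    }
    if (nrow(tr$cells))
      cell_rows[[length(cell_rows) + 1L]] <- cbind(
        well_id = tr$field_id$well_id, field_index = tr$field_id$field_index,
        tr$cells)
    if (nrow(tr$droplets))
      drop_rows[[length(drop_rows) + 1L]] <- cbind(
        well_id = tr$field_id$well_id, field_index = tr$field_id$field_index,
        tr$droplets)
  }
  cells_csv <- file.path(out_dir, sprintf("%s_truth_cells.csv", design$plate_id))
  drops_csv <- file.path(out_dir, sprintf("%s_truth_droplets.csv", design$plate_id))
  empty_cells <- data.frame(well_id = character(0), field_index = integer(0),
                            cell_id = integer(0), row = numeric(0),
                            col = numeric(0), nucleus_radius = numeric(0),
                            is_adipocyte = logical(0))
  empty_drops <- data.frame(well_id = character(0), field_index = integer(0),
                            droplet_id = integer(0), cell_id = integer(0),
                            row = numeric(0), col = numeric(0),
                            radius = numeric(0), area = numeric(0),
                            peak_intensity = numeric(0))
  write.csv(if (length(cell_rows)) do.call(rbind, cell_rows) else
    empty_cells, cells_csv, row.names = FALSE)
  write.csv(if (length(drop_rows)) do.call(rbind, drop_rows) else
    empty_drops, drops_csv, row.names = FALSE)
  add_file(cells_csv); add_file(drops_csv)
  design_json <- file.path(out_dir, sprintf("%s_design.json", design$plate_id))
  write_plate_design(design, design_json)
  add_file(design_json)
  manifest <- list(
    plate_id = design$plate_id,
    n_fields = length(truths),
    n_images = n_images,
    conventions = list(coordinates = "0-based (row, col) pixels",
                       areas = "pixel counts", intensities = "a.u."),
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  manifest_path <- file.path(out_dir, sprintf("%s_manifest.json", design$plate_id))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}
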