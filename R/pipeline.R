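# Directory-level pipeline steps: the plumbing behind the command-line
# interface (inst/cli/adiposcreen). Each step reads and writes plain
# files (TIFF / CSV / JSON) keyed by (plate, well, field).

#' Simulate and write a full plate to disk
#'
#' Convenience wrapper: [design_plate()] -> [simulate_truth()] ->
#' [render_field()] -> [write_plate()].
#'
#' @param samples sample ids for the plate.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param model effect model (single or named list, see
#'   [simulate_truth()]).
#' @param config an [imaging_config()].
#' @param cells_per_field cells per field.
#' @param ... passed to [design_plate()].
#' @return manifest path, invisibly.
#' @export
simulate_plate_to_dir <- function(samples, out_dir, seed = 1L,
                                  model = effect_model(),
                                  config = imaging_config(),
                                  cells_per_field = 80L, ...) {
  design <- design_plate(samples, seed = seed, ...)
  truths <- simulate_truth(design, model, cells_per_field = cells_per_field,
                           config = config, seed = child_seed(seed, 1L))
  images <- lapply(seq_along(truths), function(i)
    render_field(truths[[i]], config, seed = child_seed(seed, 1000L + i)))
  write_plate(design, truths, images, out_dir)
}

#' Segment every field of a written plate
#'
#' Reads the `{plate}_{well}_{field}_{channel}.tiff` pairs of a
#' directory, segments each field, and writes per-field object tables
#' and image endpoints as CSV.
#'
#' @param image_dir directory holding the TIFFs.
#' @param out_dir output directory for `object_*.csv` and
#'   `endpoints.csv`.
#' @param params a [segmentation_params()].
#' @return the endpoints data.frame, invisibly.
#' @export
segment_plate_dir <- function(image_dir, out_dir,
                              params = segmentation_params()) {
  nuc_files <- sort(list.files(image_dir, "_nuclei\\.tiff$",
                               full.names = TRUE))
  if (!length(nuc_files)) stop("no *_nuclei.tiff in ", image_dir, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ep_rows <- list(); drop_rows <- list(); nuc_rows <- list()
  for (nf in nuc_files) {
    lf <- sub("_nuclei\\.tiff$", "_lipid.tiff", nf)
    if (!file.exists(lf)) stop("missing lipid channel for ", nf, call. = FALSE)
    stem <- sub("_nuclei\\.tiff$", "", basename(nf))
    parts <- strsplit(stem, "_")[[1]]
    key <- data.frame(plate = parts[1], well = parts[2],
                      field = as.integer(parts[3]))
    imgs <- list(nuclei = read_tiff(nf), lipid = read_tiff(lf),
                 field_id = list(well_id = key$well, field_index = key$field))
    tabs <- segment_field(imgs, params)
    ep_rows[[stem]] <- cbind(key, compute_image_endpoints(tabs))
    if (nrow(tabs$droplets)) drop_rows[[stem]] <- cbind(key, tabs$droplets)
    if (nrow(tabs$nuclei)) nuc_rows[[stem]] <- cbind(key, tabs$nuclei)
  }
  endpoints <- do.call(rbind, ep_rows)
  rownames(endpoints) <- NULL
  write.csv(endpoints, file.path(out_dir, "endpoints.csv"), row.names = FALSE)
  write.csv(do.call(rbind, nuc_rows), file.path(out_dir, "object_nuclei.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, drop_rows),
            file.path(out_dir, "object_droplets.csv"), row.names = FALSE)
  invisible(endpoints)
}
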