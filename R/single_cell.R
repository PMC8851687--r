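#' Classify cells into preadipocytes and adipocytes
#'
#' An adipocyte is operationally a cell containing at least one assigned
#' lipid droplet. Per cell the summed droplet area (`lipid_area`), the
#' droplet count and the average staining intensity per lipid pixel
#' (`avg_intensity` = total assigned droplet intensity / total assigned
#' droplet area) are computed. Unassigned droplets (`cell_id` NA)
#' contribute to no cell; they still count in image endpoints.
#'
#' @param cells data.frame with a `cell_id` column (e.g. the `cells`
#'   table of [segment_field()]).
#' @param droplets droplet data.frame with `cell_id`, `area`,
#'   `integrated_intensity`.
#' @return data.frame of `adipocyte_record`s: cell_id, droplet_count,
#'   lipid_area, avg_intensity, is_adipocyte, is_mature (FALSE until
#'   [flag_mature()]), norm_intensity (NA until [normalize_intensity()]).
#' @export
classify_adipocytes <- function(cells, droplets) {
  assigned <- droplets[!is.na(droplets$cell_id), , drop = FALSE]
  if (nrow(assigned) && !all(assigned$cell_id %in% cells$cell_id))
    stop("droplet references unknown cell_id", call. = FALSE)
  agg_count <- tapply(assigned$area, assigned$cell_id, length)
  agg_area <- tapply(assigned$area, assigned$cell_id, sum)
  agg_int <- tapply(assigned$integrated_intensity, assigned$cell_id, sum)
  rec <- data.frame(cell_id = cells$cell_id, droplet_count = 0L,
                    lipid_area = 0, avg_intensity = NA_real_,
                    is_adipocyte = FALSE, is_mature = FALSE,
                    norm_intensity = NA_real_)
  if (length(agg_count)) {
    ids <- as.integer(names(agg_count))
    m <- match(ids, rec$cell_id)
    rec$droplet_count[m] <- as.integer(agg_count)
    rec$lipid_area[m] <- as.numeric(agg_area)
    rec$avg_intensity[m] <- as.numeric(agg_int) / as.numeric(agg_area)
    rec$is_adipocyte[m] <- TRUE
  }
  rec
}

#' Flag mature adipocytes
#'
#' A mature adipocyte carries a summed lipid-droplet area of at least
#' `mature_area_threshold` pixels (default 1000 px, i.e. eight
#' average-sized droplets of ~125 px). The threshold is inclusive.
#'
#' @param records output of [classify_adipocytes()].
#' @param mature_area_threshold area threshold in pixels.
#' @return records with `is_mature` set.
#' @export
flag_mature <- function(records, mature_area_threshold = 1000) {
  records$is_mature <- records$is_adipocyte &
    records$lipid_area >= mature_area_threshold
  records
}

#' Normalize per-adipocyte intensity to the plate reference
#'
#' Divides each adipocyte's average intensity by the mean average
#' intensity over all adipocytes in the plate's internal reference wells
#' (cells treated with 300 nM rosiglitazone), pooled across reference
#' wells. This controls for cross-plate staining differences.
#' Preadipocytes keep `norm_intensity` NA.
#'
#' @param records adipocyte records for the plate.
#' @param reference_records adipocyte records from the plate's reference
#'   wells (may be a subset of `records`).
#' @param plate_id used in the error message when no reference
#'   adipocytes exist.
#' @return records with `norm_intensity` filled in.
#' @export
normalize_intensity <- function(records, reference_records,
                                plate_id = "plate") {
  ref <- reference_records[reference_records$is_adipocyte, , drop = FALSE]
  if (!nrow(ref))
    stop(sprintf("no reference adipocytes on %s: cannot normalize intensity",
                 plate_id), call. = FALSE)
  ref_mean <- mean(ref$avg_intensity)
  records$norm_intensity <- ifelse(records$is_adipocyte,
                                   records$avg_intensity / ref_mean,
                                   NA_real_)
  records
}

#' Summarize the cell population of a well
#'
#' Counts preadipocytes, adipocytes and mature adipocytes and reports
#' median lipid area and median normalized intensity over adipocytes
#' only (NA when the well has none; even-length medians are the mean of
#' the central pair, as in [stats::median()]).
#'
#' @param records adipocyte records of one well.
#' @param well_id identifier carried into the summary.
#' @return one-row data.frame: well_id, n_cells, n_preadipocytes,
#'   n_adipocytes, n_mature, median_lipid_area, median_norm_intensity.
#' @export
summarize_population <- function(records, well_id = NA_character_) {
  adi <- records[records$is_adipocyte, , drop = FALSE]
  data.frame(
    well_id = well_id,
    n_cells = nrow(records),
    n_preadipocytes = sum(!records$is_adipocyte),
    n_adipocytes = nrow(adi),
    n_mature = sum(adi$is_mature),
    median_lipid_area = if (nrow(adi)) stats::median(adi$lipid_area) else NA_real_,
    median_norm_intensity = if (nrow(adi) && any(!is.na(adi$norm_intensity)))
      stats::median(adi$norm_intensity, na.rm = TRUE) else NA_real_)
}
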