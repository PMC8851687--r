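#' Serial-dilution dose series
#'
#' @param top_dose highest dose (mg plastic/well for extracts, nM for the
#'   reference compound).
#' @param n_concentrations number of dose levels (>= 1).
#' @param dilution_factor fold dilution between consecutive levels (> 1,
#'   default 2 for a 1:2 series).
#' @return numeric vector of doses, highest first:
#'   `top_dose / dilution_factor^(0:(n-1))`.
#' @examples
#' dose_series(3, 5, 2) # 3 1.5 0.75 0.375 0.1875
#' @export
dose_series <- function(top_dose, n_concentrations, dilution_factor = 2) {
  stopifnot_scalar_number(top_dose, "top_dose", positive = TRUE)
  if (n_concentrations < 1) stop("n_concentrations must be >= 1", call. = FALSE)
  if (n_concentrations > 1 && dilution_factor <= 1)
    stop("dilution_factor must be > 1", call. = FALSE)
  top_dose / dilution_factor^(seq_len(n_concentrations) - 1)
}

well_ids_96 <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Design one 96-well screening plate
#'
#' Lays out test samples in serial dilution with replicates together with
#' the control block every plate carries: vehicle (solvent) wells,
#' negative (medium only) wells, undifferentiated preadipocyte wells and
#' a reference-compound (rosiglitazone) dilution series whose top dose is
#' always present. The assignment of treatments to physical wells is a
#' seed-deterministic random permutation so position effects cannot align
#' with treatment.
#'
#' @param samples character vector of sample ids to place on this plate.
#' @param top_dose,n_concentrations,dilution_factor sample dose series,
#'   see [dose_series()]. Defaults: 3 mg plastic/well, 5 levels, 1:2.
#' @param replicates wells per (sample, dose), default 4.
#' @param seed integer seed controlling the layout permutation.
#' @param plate_id plate identifier string.
#' @param controls list overriding the control block:
#'   `n_vehicle`, `n_negative`, `n_preadipocyte`,
#'   `reference_top_dose` (nM), `reference_n`, `reference_dilution`,
#'   `reference_replicates`.
#' @return A `plate_design` object: list with `plate_id`, `wells` (a
#'   data.frame with `well_id`, `treatment`, `sample_id`, `dose`,
#'   `replicate_index`) and `meta`.
#' @examples
#' pd <- design_plate(paste0("S", 1:4), seed = 1)
#' table(pd$wells$treatment)
#' @export
design_plate <- function(samples, top_dose = 3, n_concentrations = 5,
                         dilution_factor = 2, replicates = 4, seed = 1L,
                         plate_id = "P1", controls = list()) {
  ctl <- utils::modifyList(list(
    n_vehicle = 4L, n_negative = 4L, n_preadipocyte = 2L,
    reference_top_dose = 300, reference_n = 5L, reference_dilution = 2,
    reference_replicates = 1L
  ), controls)
  doses <- dose_series(top_dose, n_concentrations, dilution_factor)
  ref_doses <- dose_series(ctl$reference_top_dose, ctl$reference_n,
                           ctl$reference_dilution)
  rows <- list()
  add <- function(treatment, sample_id, dose, rep_idx) {
    rows[[length(rows) + 1L]] <<- data.frame(
      treatment = treatment, sample_id = sample_id, dose = dose,
      replicate_index = rep_idx, stringsAsFactors = FALSE)
  }
  for (s in samples)
    for (d in doses)
      for (k in seq_len(replicates)) add("sample", s, d, k)
  for (k in seq_len(ctl$n_vehicle)) add("vehicle", NA_character_, 0, k)
  for (k in seq_len(ctl$n_negative)) add("negative", NA_character_, 0, k)
  for (k in seq_len(ctl$n_preadipocyte)) add("preadipocyte_control", NA_character_, 0, k)
  for (d in ref_doses)
    for (k in seq_len(ctl$reference_replicates)) add("reference", "rosiglitazone", d, k)
  wells <- do.call(rbind, rows)
  ids <- well_ids_96()
  if (nrow(wells) > length(ids))
    stop(sprintf(
      "plate capacity exceeded: %d treatment wells requested but only %d wells available (shortfall %d)",
      nrow(wells), length(ids), nrow(wells) - length(ids)), call. = FALSE)
  n_blank <- length(ids) - nrow(wells)
  if (n_blank > 0) {
    blank <- data.frame(treatment = "blank", sample_id = NA_character_,
                        dose = 0, replicate_index = seq_len(n_blank),
                        stringsAsFactors = FALSE)
    wells <- rbind(wells, blank)
  }
  perm <- with_seed(seed, sample.int(length(ids)))
  wells <- wells[order(perm), , drop = FALSE]
  wells <- cbind(well_id = ids, wells)
  rownames(wells) <- NULL
  structure(list(plate_id = plate_id, wells = wells,
                 meta = list(top_dose = top_dose,
                             n_concentrations = n_concentrations,
                             dilution_factor = dilution_factor,
                             replicates = replicates, seed = seed,
                             controls = ctl)),
            class = "plate_design")
}

#' @export
print.plate_design <- function(x, ...) {
  cat(sprintf("<plate_design %s: %d wells>\n", x$plate_id, nrow(x$wells)))
  print(table(x$wells$treatment))
  invisible(x)
}

#' Design a multi-plate screen
#'
#' Splits a sample list over as many 96-well plates as needed (default
#' four samples per plate so that 4 samples x 5 doses x 4 replicates plus
#' the control block fill one plate) and designs each plate with a seed
#' derived from the screen seed.
#'
#' @inheritParams design_plate
#' @param samples_per_plate samples placed on each plate.
#' @return list of [design_plate()] results.
#' @export
design_screen <- function(samples, samples_per_plate = 4L, seed = 1L, ...) {
  groups <- split(samples, ceiling(seq_along(samples) / samples_per_plate))
  lapply(seq_along(groups), function(i) {
    design_plate(groups[[i]], seed = child_seed(seed, i),
                 plate_id = sprintf("P%02d", i), ...)
  })
}

#' Write / read a plate design as JSON
#'
#' Plate layouts travel as JSON (one object with `plate_id`, `meta` and
#' a records-style `wells` array).
#' @param design a `plate_design`.
#' @param path file path ending in `.json`.
#' @return `write_plate_design()` returns `path` invisibly;
#'   `read_plate_design()` returns a `plate_design`.
#' @export
write_plate_design <- function(design, path) {
  jsonlite::write_json(
    list(plate_id = design$plate_id, meta = design$meta, wells = design$wells),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_plate_design
#' @export
read_plate_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  wells <- obj$wells
  wells$sample_id <- as.character(wells$sample_id)
  wells$sample_id[wells$sample_id == "NULL"] <- NA_character_
  structure(list(plate_id = obj$plate_id, wells = wells, meta = obj$meta),
            class = "plate_design")
}

#' Dose-unit conversions for plastic-extract assays
#'
#' The assay expresses doses as "plastic equivalents": the chemicals
#' extracted from a given mass of plastic. Extraction of 3 g of plastic
#' into a final volume of 200 uL means 1 uL of extract carries the
#' chemicals of 15 mg of plastic; a 200 uL culture well converts
#' mg-plastic/well into mg-plastic/mL by dividing by 0.2.
#'
#' @param value numeric vector of doses.
#' @param from,to one of `"mg_per_well"`, `"mg_per_mL"`, `"uL_extract"`.
#' @param well_volume_uL culture volume per well (default 200).
#' @param mg_per_uL_extract plastic equivalent of 1 uL extract
#'   (default 15 = 3000 mg / 200 uL).
#' @return converted numeric vector.
#' @examples
#' convert_dose(3, "mg_per_well", "mg_per_mL")   # 15
#' convert_dose(1, "uL_extract", "mg_per_well")  # 15
#' @export
convert_dose <- function(value, from, to, well_volume_uL = 200,
                         mg_per_uL_extract = 15) {
  units <- c("mg_per_well", "mg_per_mL", "uL_extract")
  if (!from %in% units || !to %in% units)
    stop("unknown dose unit; use one of: ", paste(units, collapse = ", "),
         call. = FALSE)
  # hub unit: mg plastic per well
  mg <- switch(from,
    mg_per_well = value,
    mg_per_mL   = value * (well_volume_uL / 1000),
    uL_extract  = value * mg_per_uL_extract)
  switch(to,
    mg_per_well = mg,
    mg_per_mL   = mg / (well_volume_uL / 1000),
    uL_extract  = mg / mg_per_uL_extract)
}

#' Extraction and dilution arithmetic
#'
#' `extract_equivalent()` gives mg plastic represented by 1 uL of
#' extract for a given extraction; `solvent_percent()` gives the final
#' solvent concentration (%, v/v) after diluting the extract into medium.
#'
#' @param mass_g plastic mass extracted (g).
#' @param final_volume_uL extract volume after concentration (uL).
#' @param dilution_fold dilution of extract into medium.
#' @return numeric scalar.
#' @examples
#' extract_equivalent(3, 200)  # 15 mg plastic per uL extract
#' solvent_percent(1000)       # 0.1 (% v/v)
#' @export
extract_equivalent <- function(mass_g = 3, final_volume_uL = 200) {
  mass_g * 1000 / final_volume_uL
}

#' @rdname extract_equivalent
#' @export
solvent_percent <- function(dilution_fold) 100 / dilution_fold
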