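#' Blank-filter a nontarget feature table
#'
#' A feature is retained for a sample when its abundance is strictly
#' more than `fold_threshold` times the blank abundance (maximum over
#' blank columns by default, mean optionally), or when it is absent from
#' every blank and present in the sample ("only present in samples").
#' Exactly `fold_threshold`-fold is not retained (strict inequality).
#'
#' @param table feature table data.frame: `feature_id`, `mz`, `rt`,
#'   `has_ms2`, `best_id_name`, `best_id_cid`, `id_score`, plus one
#'   abundance column per sample and per blank.
#' @param sample_cols names of the sample abundance columns.
#' @param blank_cols names of the blank abundance columns (>= 1).
#' @param fold_threshold fold change over blanks (default 10).
#' @param blank_agg aggregate across blank columns: `"max"` (default,
#'   conservative) or `"mean"`.
#' @return named list (one element per sample) of data.frames with the
#'   retained features; each carries the sample's abundance in an
#'   `abundance` column.
#' @export
filter_features <- function(table, sample_cols, blank_cols,
                            fold_threshold = 10,
                            blank_agg = c("max", "mean")) {
  blank_agg <- match.arg(blank_agg)
  if (length(blank_cols) < 1)
    stop("need at least one blank column", call. = FALSE)
  missing_cols <- setdiff(c(sample_cols, blank_cols), names(table))
  if (length(missing_cols))
    stop("columns not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bl <- as.matrix(table[, blank_cols, drop = FALSE])
  if (any(bl < 0, na.rm = TRUE)) stop("abundances must be >= 0", call. = FALSE)
  blank_ref <- if (blank_agg == "max") apply(bl, 1, max) else rowMeans(bl)
  blank_all_zero <- apply(bl, 1, function(x) all(x == 0))
  out <- list()
  meta_cols <- setdiff(names(table), c(sample_cols, blank_cols))
  for (s in sample_cols) {
    ab <- table[[s]]
    keep <- (ab > fold_threshold * blank_ref) | (blank_all_zero & ab > 0)
    sub <- table[keep, meta_cols, drop = FALSE]
    sub$abundance <- ab[keep]
    rownames(sub) <- NULL
    out[[s]] <- sub
  }
  out
}

#' Summarize the retained features of one sample
#'
#' The per-sample triage summary: total retained features, features with
#' a fragmentation (MS2) spectrum, features identified at or above the
#' score threshold, and the identified share of MS2 features as a
#' one-decimal percentage (NA when no MS2 features exist).
#'
#' @param retained data.frame of retained features for one sample (an
#'   element of [filter_features()] output).
#' @param score_threshold identification-score cutoff, inclusive
#'   (default 40).
#' @param sample sample name carried into the row.
#' @return one-row data.frame: sample, n_features, n_ms2,
#'   n_id_ge_threshold, pct_of_ms2.
#' @export
summarize_sample <- function(retained, score_threshold = 40,
                             sample = NA_character_) {
  n_features <- nrow(retained)
  n_ms2 <- sum(retained$has_ms2)
  n_id <- sum(retained$has_ms2 & !is.na(retained$id_score) &
                retained$id_score >= score_threshold)
  pct <- if (n_ms2 > 0) round(100 * n_id / n_ms2, 1) else NA_real_
  data.frame(sample = sample, n_features = n_features, n_ms2 = n_ms2,
             n_id_ge_threshold = n_id, pct_of_ms2 = pct)
}

#' Load the curated MDC reference list
#'
#' Ships with a small curated stand-in for the full published list of
#' known adipogenic (metabolism-disrupting) chemicals: the eleven
#' compounds reported as tentatively identified in the screened plastic
#' products, keyed by PubChem-style CID with an abbreviation and full
#' name. The file (`extdata/mdc_list_synthetic.csv`) is a synthetic
#' curation — CIDs are best-effort — and users extend or replace it with
#' their own CSV of the same three columns.
#'
#' @param path CSV with columns `abbreviation`, `name`, `cid`; defaults
#'   to the shipped list.
#' @return data.frame with unique CIDs.
#' @export
mdc_list <- function(path = system.file("extdata", "mdc_list_synthetic.csv",
                                        package = "adipoScreen")) {
  mdc <- read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(mdc$cid)) stop("MDC list CIDs must be unique", call. = FALSE)
  mdc
}

#' Cross-reference identified features against the MDC list
#'
#' Matches retained, confidently identified features (id_score >=
#' `score_threshold`) to MDC-list entries by CID; features without a CID
#' fall back to a case-insensitive name match with a warning. Returns
#' the sorted, de-duplicated abbreviations.
#'
#' @param retained retained features of one sample.
#' @param mdc MDC list ([mdc_list()]).
#' @param score_threshold inclusive score cutoff (default 40).
#' @return character vector of MDC abbreviations (possibly empty).
#' @export
cross_reference_mdc <- function(retained, mdc = mdc_list(),
                                score_threshold = 40) {
  idd <- retained[retained$has_ms2 & !is.na(retained$id_score) &
                    retained$id_score >= score_threshold, , drop = FALSE]
  if (!nrow(idd)) return(character(0))
  hits <- mdc$abbreviation[mdc$cid %in% idd$best_id_cid]
  no_cid <- idd[is.na(idd$best_id_cid) & !is.na(idd$best_id_name), ,
                drop = FALSE]
  if (nrow(no_cid)) {
    nm <- tolower(no_cid$best_id_name)
    name_hits <- mdc$abbreviation[tolower(mdc$name) %in% nm]
    if (length(name_hits))
      warning("MDC matched by name only (no CID): ",
              paste(name_hits, collapse = ", "), call. = FALSE)
    hits <- c(hits, name_hits)
  }
  sort(unique(hits))
}

#' Triage a whole feature table into a summary table
#'
#' Runs [filter_features()], [summarize_sample()] and
#' [cross_reference_mdc()] over every sample column.
#'
#' @inheritParams filter_features
#' @param mdc MDC list.
#' @param score_threshold identification-score cutoff.
#' @param products optional named character vector mapping sample to
#'   product description.
#' @return data.frame, one row per sample: sample, product, n_features,
#'   n_ms2, n_id_ge_threshold, pct_of_ms2, mdc_hits
#'   (comma-joined abbreviations).
#' @export
triage_features <- function(table, sample_cols, blank_cols,
                            fold_threshold = 10, score_threshold = 40,
                            mdc = mdc_list(), products = NULL) {
  retained <- filter_features(table, sample_cols, blank_cols, fold_threshold)
  rows <- lapply(sample_cols, function(s) {
    sm <- summarize_sample(retained[[s]], score_threshold, sample = s)
    sm$product <- unname(products[s] %||% NA_character_)
    sm$mdc_hits <- paste(cross_reference_mdc(retained[[s]], mdc,
                                             score_threshold),
                         collapse = ", ")
    sm
  })
  out <- do.call(rbind, rows)
  out[, c("sample", "product", "n_features", "n_ms2", "n_id_ge_threshold",
          "pct_of_ms2", "mdc_hits")]
}

#' Write the triage summary as a publication-style CSV
#'
#' Column order: sample, product, n_features, n_ms2, n_id_ge_40,
#' pct_of_ms2 (formatted with one decimal), mdc_hits. An empty summary
#' produces a header-only file.
#'
#' @param summaries data.frame from [triage_features()] (or rbind of
#'   [summarize_sample()] rows).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table1 <- function(summaries, path) {
  cols <- c("sample", "product", "n_features", "n_ms2", "n_id_ge_40",
            "pct_of_ms2", "mdc_hits")
  out <- data.frame(
    sample = summaries$sample %||% character(0),
    product = summaries$product %||% NA_character_,
    n_features = summaries$n_features,
    n_ms2 = summaries$n_ms2,
    n_id_ge_40 = summaries$n_id_ge_threshold,
    pct_of_ms2 = ifelse(is.na(summaries$pct_of_ms2), "",
                        sprintf("%.1f", summaries$pct_of_ms2)),
    mdc_hits = summaries$mdc_hits %||% "")
  if (!nrow(summaries))
    out <- out[0, , drop = FALSE]
  names(out) <- cols
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Printed per-sample nontarget-analysis counts
#'
#' The published per-sample feature counts (total retained, with MS2,
#' identified at score >= 40, percent of MS2) and reported MDC hits for
#' the 34 plastic products, shipped as plain CSV. One product was not
#' analyzed (NA row). Used as the reference input for the synthetic
#' feature-table generator and the triage arithmetic checks.
#'
#' @return data.frame with columns sample, product, n_features, n_ms2,
#'   n_id_ge_40, pct_of_ms2, mdc_hits.
#' @export
table1_counts <- function() {
  read.csv(system.file("extdata", "table1_counts.csv",
                       package = "adipoScreen"),
           stringsAsFactors = FALSE)
}

#' Simulate a feature table matching given per-sample counts
#'
#' Builds a wide nontarget feature table whose triage reproduces a
#' given count structure exactly: for each sample, `n_features` features
#' that pass the blank filter (of which `n_ms2` carry MS2 spectra and
#' `n_id_ge_40` score >= 40), plus per-sample decoys that must be
#' removed by the filter (blank-dominated and exactly-10-fold features).
#' Samples with reported MDC hits get one qualifying identified feature
#' per hit carrying the matching CID.
#'
#' @param counts data.frame like [table1_counts()] (NA rows skipped).
#' @param n_blanks number of procedure-blank columns.
#' @param n_decoys blank-dominated decoy features per sample.
#' @param mdc MDC list used to look up hit CIDs.
#' @param seed integer seed.
#' @return list: `table` (the wide feature table), `sample_cols`,
#'   `blank_cols`.
#' @export
simulate_feature_table <- function(counts, n_blanks = 3, n_decoys = 5,
                                   mdc = mdc_list(), seed = 1L) {
  counts <- counts[!is.na(counts$n_features), , drop = FALSE]
  sample_cols <- counts$sample
  blank_cols <- paste0("PB", seq_len(n_blanks))
  with_seed(seed, {
    per_sample <- lapply(seq_len(nrow(counts)), function(i) {
      s <- counts$sample[i]
      n_feat <- counts$n_features[i]
      n_ms2 <- counts$n_ms2[i]
      n_id <- counts$n_id_ge_40[i]
      hits <- counts$mdc_hits[i]
      hit_ab <- if (!is.na(hits) && nzchar(hits))
        trimws(strsplit(hits, ",")[[1]]) else character(0)
      if (!all(hit_ab %in% mdc$abbreviation))
        stop("unknown MDC abbreviation: ",
             paste(setdiff(hit_ab, mdc$abbreviation), collapse = ", "),
             call. = FALSE)
      n_hit <- min(length(hit_ab), n_id)
      n_gen <- n_id - n_hit              # generic identifications
      n_low <- n_ms2 - n_id              # MS2 below the score threshold
      n_noms2 <- n_feat - n_ms2          # retained, no MS2
      n_noms2_blanky <- n_noms2 %/% 2    # >10x over non-zero blanks
      n_noms2_clean <- n_noms2 - n_noms2_blanky
      n <- as.integer(n_feat + n_decoys + 1L) # + one exactly-10-fold decoy
      hit_idx <- match(hit_ab[seq_len(n_hit)], mdc$abbreviation)
      grp <- rep(c("hit", "gen", "low", "clean", "blanky", "decoy", "ten"),
                 c(n_hit, n_gen, n_low, n_noms2_clean, n_noms2_blanky,
                   n_decoys, 1L))
      has_ms2 <- grp %in% c("hit", "gen", "low")
      id_score <- ifelse(grp %in% c("hit", "gen"),
                         round(runif(n, 40, 95), 1),
                         ifelse(grp == "low", round(runif(n, 0, 39.9), 1),
                                NA_real_))
      cid <- rep(NA_real_, n)
      cid[grp == "hit"] <- mdc$cid[hit_idx]
      cid[grp == "gen"] <- 1e6 + seq_len(n_gen)
      name <- rep(NA_character_, n)
      name[grp == "hit"] <- mdc$name[hit_idx]
      name[grp == "gen"] <- sprintf("compound_%s_%d", gsub(" ", "", s),
                                    seq_len(n_gen))
      name[grp == "low"] <- sprintf("lowscore_%s_%d", gsub(" ", "", s),
                                    seq_len(n_low))
      blank_max <- numeric(n)
      blank_max[grp == "blanky"] <- runif(n_noms2_blanky, 10, 100)
      blank_max[grp %in% c("decoy", "ten")] <- runif(n_decoys + 1L, 100, 1000)
      abundance <- runif(n, 1e4, 1e6)
      abundance[grp == "blanky"] <- blank_max[grp == "blanky"] *
        runif(n_noms2_blanky, 10.5, 50)
      abundance[grp == "decoy"] <- blank_max[grp == "decoy"] *
        runif(n_decoys, 0.1, 10)
      abundance[grp == "ten"] <- blank_max[grp == "ten"] * 10 # not ">10x"
      list(sample = s, n = n, has_ms2 = has_ms2, id_score = id_score,
           cid = cid, name = name, blank_max = blank_max,
           abundance = abundance)
    })
    n_total <- sum(vapply(per_sample, `[[`, integer(1), "n"))
    tab <- data.frame(
      feature_id = sprintf("F%06d", seq_len(n_total)),
      mz = round(runif(n_total, 100, 900), 4),
      rt = round(runif(n_total, 0.5, 20), 2),
      has_ms2 = unlist(lapply(per_sample, `[[`, "has_ms2")),
      best_id_name = unlist(lapply(per_sample, `[[`, "name")),
      best_id_cid = unlist(lapply(per_sample, `[[`, "cid")),
      id_score = unlist(lapply(per_sample, `[[`, "id_score")),
      stringsAsFactors = FALSE, check.names = FALSE)
    ab <- matrix(0, n_total, length(sample_cols) + n_blanks,
                 dimnames = list(NULL, c(sample_cols, blank_cols)))
    offset <- 0L
    for (ps in per_sample) {
      rows <- offset + seq_len(ps$n)
      ab[rows, ps$sample] <- ps$abundance
      # spread the blank signal: the max in blank 1, half of it elsewhere
      ab[rows, blank_cols[1]] <- ps$blank_max
      if (n_blanks > 1)
        for (b in blank_cols[-1]) ab[rows, b] <- ps$blank_max / 2
      offset <- offset + ps$n
    }
    tab <- cbind(tab, as.data.frame(ab, check.names = FALSE))
    list(table = tab, sample_cols = sample_cols, blank_cols = blank_cols)
  })
}
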