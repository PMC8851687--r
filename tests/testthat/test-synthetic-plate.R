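test_that("effect_model validates its bounds", {
  expect_s3_class(effect_model(), "effect_model")
  expect_error(effect_model(base_frac = 0.7, max_frac = 0.5), "base_frac")
  expect_error(effect_model(ec50 = -1), "ec50")
  expect_error(effect_model(maturity_boost = -0.1), "maturity_boost")
})

test_that("simulated adipocyte fractions follow the Hill curve", {
  m <- effect_model(ec50 = 1, hill = 2, base_frac = 0, max_frac = 1,
                    droplet_count_mean = 1)
  # dose 0, base 0: nobody differentiates
  tr0 <- simulate_field_truth(50, adipocyte_fraction(m, 0), m,
                              config = cfg_small(), seed = 1)
  expect_false(any(tr0$cells$is_adipocyte))
  expect_equal(nrow(tr0$droplets), 0)
  # at dose = ec50 the fraction is 0.5 within binomial 99% bounds
  big <- imaging_config(field_shape = c(1024L, 1024L))
  n_tot <- 0; n_adi <- 0
  for (f in 1:4) {
    tr <- simulate_field_truth(1400, adipocyte_fraction(m, 1), m, dose = 1,
                               config = big, seed = 100 + f,
                               cell_min_distance = 12, droplet_min_gap = -1)
    n_tot <- n_tot + nrow(tr$cells)
    n_adi <- n_adi + sum(tr$cells$is_adipocyte)
  }
  expect_gte(n_tot, 5000)
  bounds <- qbinom(c(0.005, 0.995), n_tot, 0.5)
  expect_gte(n_adi, bounds[1])
  expect_lte(n_adi, bounds[2])
})

test_that("saturating dose reaches max_frac within binomial bounds", {
  m <- effect_model(ec50 = 1, hill = 2, base_frac = 0, max_frac = 0.8,
                    droplet_count_mean = 1)
  big <- imaging_config(field_shape = c(1024L, 1024L))
  n_tot <- 0; n_adi <- 0
  for (f in 1:4) {
    tr <- simulate_field_truth(1400, adipocyte_fraction(m, 1e6), m,
                               dose = 1e6, config = big, seed = 200 + f,
                               cell_min_distance = 12, droplet_min_gap = -1)
    n_tot <- n_tot + nrow(tr$cells)
    n_adi <- n_adi + sum(tr$cells$is_adipocyte)
  }
  bounds <- qbinom(c(0.005, 0.995), n_tot, 0.8)
  expect_gte(n_adi, bounds[1])
  expect_lte(n_adi, bounds[2])
})

test_that("truth respects separation and bounds invariants", {
  cfg <- cfg_small()
  for (seed in 1:5) {
    tr <- simulate_field_truth(20, 0.6, config = cfg, seed = seed,
                               cell_min_distance = 24, droplet_min_gap = 3)
    cl <- tr$cells
    if (nrow(cl) > 1) {
      d <- as.matrix(dist(cl[, c("row", "col")]))
      diag(d) <- Inf
      expect_gte(min(d), 24)
    }
    # non-adipocytes own no droplets
    expect_true(all(tr$droplets$cell_id %in% cl$cell_id[cl$is_adipocyte]))
    # droplet discs inside the field
    dr <- tr$droplets
    if (nrow(dr)) {
      expect_true(all(dr$row - dr$radius >= 0))
      expect_true(all(dr$row + dr$radius <= cfg$field_shape[1] - 1))
      expect_true(all(dr$col - dr$radius >= 0))
      expect_true(all(dr$col + dr$radius <= cfg$field_shape[2] - 1))
      if (nrow(dr) > 1) { # pairwise edge gap
        dd <- as.matrix(dist(dr[, c("row", "col")]))
        gap <- dd - outer(dr$radius, dr$radius, "+")
        diag(gap) <- Inf
        expect_gte(min(gap), 3 - 1e-9)
      }
    }
  }
})

test_that("rendering: empty field is uniform background, renders are deterministic", {
  cfg <- cfg_small()
  im <- render_field(manual_truth(), cfg)
  expect_true(all(im$nuclei == cfg$background_level))
  expect_true(all(im$lipid == cfg$background_level))
  tr <- simulate_field_truth(10, 0.5, config = cfg, seed = 2)
  a <- render_field(tr, cfg, seed = 5)
  b <- render_field(tr, cfg, seed = 5)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$lipid, b$lipid)
  cfg_n <- cfg_small(noise = "gaussian")
  an <- render_field(tr, cfg_n, seed = 5)
  bn <- render_field(tr, cfg_n, seed = 5)
  cn <- render_field(tr, cfg_n, seed = 6)
  expect_identical(an$lipid, bn$lipid)
  expect_false(identical(an$lipid, cn$lipid))
})

test_that("blur conserves droplet flux within 0.1%", {
  cfg <- imaging_config(field_shape = c(128L, 128L), blur_sigma = 2,
                        noise_model = "none")
  # droplets at least 3*sigma from the border
  tr <- manual_truth(droplets = manual_droplets(c(30, 64, 100),
                                                c(40, 90, 30)))
  im <- render_field(tr, cfg)
  flux <- sum(im$lipid - cfg$background_level)
  # independent flux oracle: unblurred anti-aliased coverage sums
  oracle <- 0
  for (i in 1:3) {
    d <- sqrt(outer((0:127 - tr$droplets$row[i])^2,
                    (0:127 - tr$droplets$col[i])^2, "+"))
    cov <- pmin(1, pmax(0, tr$droplets$radius[i] + 0.5 - d))
    oracle <- oracle + sum(cov) * tr$droplets$peak_intensity[i]
  }
  expect_lt(abs(flux - oracle) / oracle, 0.001)
})

test_that("out-of-bounds objects are rejected", {
  cfg <- cfg_small()
  tr <- manual_truth(cells = manual_cells(2, 128))
  expect_error(render_field(tr, cfg), "out of image bounds")
})

test_that("write_plate round-trips images, truth and manifest", {
  dir <- withr::local_tempdir()
  pd <- design_plate("S1", n_concentrations = 1, replicates = 1, seed = 1)
  cfg <- imaging_config(field_shape = c(96L, 96L), fields_per_well = 2L)
  keep <- pd$wells$well_id[pd$wells$treatment %in% c("sample", "vehicle")][1:2]
  truths <- simulate_truth(pd, effect_model(), cells_per_field = 4,
                           config = cfg, seed = 2, wells = keep)
  images <- lapply(truths, render_field, config = cfg)
  manifest <- write_plate(pd, truths, images, dir)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_equal(man$n_images, length(truths) * 2)
  tiffs <- man$files$path[grepl("\\.tiff$", man$files$path)]
  expect_length(tiffs, length(truths) * 2)
  # TIFF round trip equals the in-memory array
  i1 <- images[[1]]$nuclei
  f1 <- file.path(dir, sprintf("%s_%s_%d_nuclei.tiff", pd$plate_id,
                               truths[[1]]$field_id$well_id,
                               truths[[1]]$field_id$field_index))
  expect_identical(read_tiff(f1), i1)
  # truth CSV reproduces droplet counts per field exactly
  drops <- read.csv(file.path(dir, sprintf("%s_truth_droplets.csv",
                                           pd$plate_id)))
  for (tr in truths) {
    n_csv <- sum(drops$well_id == tr$field_id$well_id &
                   drops$field_index == tr$field_id$field_index)
    expect_equal(n_csv, nrow(tr$droplets))
  }
  expect_error(write_plate(pd, truths, rev(images), dir),
               "field_id mismatch")
})

test_that("TIFF codec round-trips 8- and 16-bit and validates range", {
  f <- withr::local_tempfile(fileext = ".tiff")
  m16 <- matrix(sample.int(65536, 300) - 1L, 15, 20)
  write_tiff(f, m16, 16L)
  expect_identical(read_tiff(f), m16)
  m8 <- matrix(sample.int(256, 48) - 1L, 6, 8)
  write_tiff(f, m8, 8L)
  expect_identical(read_tiff(f), m8)
  expect_error(write_tiff(f, matrix(-1, 2, 2)), "out of range")
  expect_error(write_tiff(f, matrix(300, 2, 2), 8L), "out of range")
})
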