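test_that("blank fields yield no objects", {
  cfg <- cfg_small()
  im <- render_field(manual_truth(), cfg)
  expect_equal(nrow(segment_nuclei(im$nuclei)$table), 0)
  expect_equal(nrow(detect_droplets(im$lipid)$table), 0)
  # noisy blank: the robust guard must not hallucinate droplets
  imn <- render_field(manual_truth(), cfg_small(noise = "gaussian", sd = 60),
                      seed = 4)
  expect_equal(nrow(detect_droplets(imn$lipid)$table), 0)
})

test_that("nuclei counts and centroids match truth on noiseless fields", {
  cfg <- cfg_small()
  tr <- simulate_field_truth(15, 0, config = cfg, seed = 21,
                             cell_min_distance = 30)
  expect_equal(nrow(tr$cells), 15)
  im <- render_field(tr, cfg)
  seg <- segment_nuclei(im$nuclei)
  expect_equal(nrow(seg$table), 15)
  # match each truth nucleus to nearest detection: within 1 px
  for (i in seq_len(15)) {
    d <- sqrt((seg$table$row - tr$cells$row[i])^2 +
                (seg$table$col - tr$cells$col[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("touching nuclei are declumped", {
  cfg <- imaging_config(field_shape = c(128L, 128L), noise_model = "none")
  # centers 1.5 radii apart: a single merged blob without declumping
  tr <- manual_truth(cells = manual_cells(c(60, 72), c(64, 64), radius = 8))
  im <- render_field(tr, cfg)
  seg <- segment_nuclei(im$nuclei)
  expect_equal(nrow(seg$table), 2)
})

test_that("droplet detection matches truth counts and area", {
  cfg <- cfg_small(shape = c(360L, 360L))
  set.seed(31)
  # 40 disjoint droplets laid on a grid with jitter
  centers <- expand.grid(row = seq(30, 330, length.out = 7)[1:7],
                         col = seq(30, 330, length.out = 6))[1:40, ]
  dr <- manual_droplets(centers$row + runif(40, -3, 3),
                        centers$col + runif(40, -3, 3),
                        radius = runif(40, 4, 7))
  im <- render_field(manual_truth(droplets = dr), cfg)
  det <- detect_droplets(im$lipid)
  expect_equal(nrow(det$table), 40)
  expect_lt(abs(sum(det$table$area) - sum(dr$area)) / sum(dr$area), 0.10)
})

test_that("min_droplet_area filter excludes small droplets", {
  cfg <- imaging_config(field_shape = c(96L, 96L), noise_model = "none")
  dr <- manual_droplets(c(30, 64), c(30, 64), radius = c(6, 3))
  im <- render_field(manual_truth(droplets = dr), cfg)
  both <- detect_droplets(im$lipid)
  expect_equal(nrow(both$table), 2)
  # raise the gate above the small droplet's ~28 px area
  one <- detect_droplets(im$lipid, segmentation_params(min_droplet_area = 50))
  expect_equal(nrow(one$table), 1)
  expect_gt(min(one$table$area), 50)
})

test_that("cell delineation partitions the field around nuclei", {
  cfg <- imaging_config(field_shape = c(128L, 128L), noise_model = "none")
  tr <- manual_truth(cells = manual_cells(c(40, 90), c(40, 90)))
  im <- render_field(tr, cfg)
  seg <- segment_nuclei(im$nuclei)
  cm <- delineate_cells(seg, im$lipid)
  expect_equal(nrow(cm$table), 2)
  # each nucleus sits inside its own cell region
  for (i in 1:2) {
    px <- round(tr$cells[i, c("row", "col")]) + 1
    expect_equal(cm$labels[px$row, px$col], i)
  }
  # regions are disjoint by construction of the label map; bounded radius
  sizes <- table(cm$labels[cm$labels > 0])
  expect_lte(max(sizes), pi * (segmentation_params()$max_cell_radius + 10)^2)
  # one nucleus, empty lipid channel -> one region containing it
  tr1 <- manual_truth(cells = manual_cells(64, 64))
  im1 <- render_field(tr1, cfg)
  cm1 <- delineate_cells(segment_nuclei(im1$nuclei), im1$lipid)
  expect_equal(nrow(cm1$table), 1)
  expect_equal(cm1$labels[65, 65], 1)
})

test_that("droplet assignment follows overlap, distance and tie rules", {
  cfg <- imaging_config(field_shape = c(160L, 160L), noise_model = "none")
  cells <- manual_cells(c(60, 100), c(80, 80), adipo = TRUE)
  # droplet fully inside cell 1's territory; droplet midway between the
  # two (equidistant -> lower id); droplet far from both (unassigned)
  drops <- manual_droplets(c(60, 80, 20), c(95, 80, 150), radius = 5)
  tr <- manual_truth(cells = cells, droplets = drops)
  im <- render_field(tr, cfg)
  seg <- segment_nuclei(im$nuclei)
  cm <- delineate_cells(seg, im$lipid,
                        segmentation_params(max_cell_radius = 20))
  det <- detect_droplets(im$lipid)
  expect_equal(nrow(det$table), 3)
  assigned <- assign_droplets(det, cm,
                              segmentation_params(max_assign_distance = 30))
  # order detections by position to identify them
  near <- function(r, c) which.min((assigned$row - r)^2 + (assigned$col - c)^2)
  expect_equal(assigned$cell_id[near(60, 95)], 1L)
  expect_equal(assigned$cell_id[near(80, 80)], 1L) # tie -> lower cell id
  expect_true(is.na(assigned$cell_id[near(20, 150)]))
  # unassigned droplets still count in image totals
  tabs <- list(nuclei = seg$table, droplets = assigned)
  ep <- compute_image_endpoints(tabs)
  expect_equal(ep$droplet_count, 3)
  expect_equal(ep$total_area, sum(assigned$area))
  expect_error(assign_droplets(det, structure(list(
    labels = matrix(0L, 10, 10)), class = "cell_map")),
    "different fields")
})

test_that("endpoints are exact sums and survive a CSV round trip", {
  empty <- list(nuclei = data.frame(), droplets =
                  data.frame(area = numeric(0),
                             integrated_intensity = numeric(0)))
  expect_equal(unlist(compute_image_endpoints(empty)),
               c(nuclei_count = 0, droplet_count = 0, total_area = 0,
                 total_intensity = 0))
  tabs <- list(
    nuclei = data.frame(nucleus_id = 1:2),
    droplets = data.frame(droplet_id = 1:3, area = c(100, 200, 300),
                          integrated_intensity = c(1.5, 2.25, 3e5)))
  ep <- compute_image_endpoints(tabs)
  expect_equal(ep$total_area, 600)
  expect_equal(ep$total_intensity, 1.5 + 2.25 + 3e5)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tabs$droplets, f, row.names = FALSE)
  tabs2 <- list(nuclei = tabs$nuclei, droplets = read.csv(f))
  expect_equal(compute_image_endpoints(tabs2), ep)
})

test_that("adding a droplet never decreases endpoints", {
  cfg <- imaging_config(field_shape = c(128L, 128L), noise_model = "none")
  base_drops <- manual_droplets(c(40, 90), c(40, 90), radius = 5)
  more_drops <- rbind(base_drops,
                      manual_droplets(64, 64, radius = 5)[1, ])
  ep1 <- compute_image_endpoints(
    list(nuclei = data.frame(),
         droplets = detect_droplets(render_field(
           manual_truth(droplets = base_drops), cfg)$lipid)$table))
  ep2 <- compute_image_endpoints(
    list(nuclei = data.frame(),
         droplets = detect_droplets(render_field(
           manual_truth(droplets = more_drops), cfg)$lipid)$table))
  expect_gte(ep2$droplet_count, ep1$droplet_count)
  expect_gte(ep2$total_area, ep1$total_area)
  expect_gte(ep2$total_intensity, ep1$total_intensity)
})

test_that("segment_field on noisy fields stays within 5% of truth", {
  cfg <- cfg_small(noise = "gaussian", sd = 600)
  n_true <- c(0, 0); n_seg <- c(0, 0)
  for (seed in 1:3) {
    tr <- simulate_field_truth(12, 0.5, config = cfg, seed = seed,
                               droplet_min_gap = 4)
    im <- render_field(tr, cfg, seed = seed)
    tabs <- segment_field(im)
    n_true <- n_true + c(nrow(tr$cells), nrow(tr$droplets))
    n_seg <- n_seg + c(nrow(tabs$nuclei), nrow(tabs$droplets))
  }
  expect_lt(abs(n_seg[1] - n_true[1]) / n_true[1], 0.05)
  expect_lt(abs(n_seg[2] - n_true[2]) / n_true[2], 0.05)
})
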