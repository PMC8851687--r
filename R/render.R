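# Field rendering: anti-aliased discs -> flux-preserving Gaussian blur
# -> constant background -> optional noise -> clip to bit depth.

# Banded Gaussian blur matrix (n x n). normalize = "flux": columns sum
# to 1 so total flux is conserved exactly (sum(K %*% x) == sum(x)); near
# edges the truncated mass folds back. normalize = "constant": rows sum
# to 1 so a constant image stays exactly constant (used for smoothing
# before thresholding, where edge bands must not appear).
blur_matrix <- function(n, sigma, normalize = c("flux", "constant")) {
  normalize <- match.arg(normalize)
  h <- max(1L, ceiling(4 * sigma))
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (d in -h:h) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) K[cbind(idx + d, idx)] <- g[d + h + 1]
    else K[cbind(idx, idx - d)] <- g[-d + h + 1]
  }
  if (normalize == "flux") sweep(K, 2, colSums(K), "/")
  else K / rowSums(K)
}

gaussian_blur <- function(img, sigma, normalize = "flux") {
  if (sigma <= 0) return(img)
  Kr <- blur_matrix(nrow(img), sigma, normalize)
  Kc <- blur_matrix(ncol(img), sigma, normalize)
  Kr %*% img %*% t(Kc)
}

# Anti-aliased disc accumulation: adds `amplitude * coverage` for a disc
# of given center/radius; coverage ramps linearly over the last pixel.
draw_disc <- function(canvas, row, col, radius, amplitude) {
  r0 <- max(1L, floor(row - radius))
  r1 <- min(nrow(canvas), ceiling(row + radius) + 1L)
  c0 <- max(1L, floor(col - radius))
  c1 <- min(ncol(canvas), ceiling(col + radius) + 1L)
  if (r0 > r1 || c0 > c1) return(canvas)
  rr <- (r0:r1) - 1 # 0-based pixel coordinates
  cc <- (c0:c1) - 1
  d <- sqrt(outer((rr - row)^2, (cc - col)^2, "+"))
  cov <- pmin(1, pmax(0, radius + 0.5 - d))
  canvas[r0:r1, c0:c1] <- canvas[r0:r1, c0:c1] + amplitude * cov
  canvas
}

#' Render the two fluorescence channels of a field
#'
#' Produces the nuclei-stain and lipid-stain channels for a
#' [simulate_field_truth()] ground truth: anti-aliased discs at the
#' nucleus and droplet positions, Gaussian optical blur (flux
#' preserving), a constant background, the configured noise model, and
#' clipping/rounding to the configured bit depth.
#'
#' @param truth a `field_truth`.
#' @param config an [imaging_config()].
#' @param seed seed for the noise draws (ignored for
#'   `noise_model = "none"`, which renders bit-identically).
#' @return a `field_images` object: list with integer matrices
#'   `nuclei` and `lipid`, plus `field_id` and `config`.
#' @export
render_field <- function(truth, config = imaging_config(), seed = 1L) {
  stopifnot(inherits(truth, "field_truth"), inherits(config, "imaging_config"))
  shape <- config$field_shape
  validate_in_bounds <- function(row, col, radius) {
    if (any(row - radius < -0.5) || any(row + radius > shape[1] - 0.5) ||
        any(col - radius < -0.5) || any(col + radius > shape[2] - 0.5))
      stop("object disc out of image bounds", call. = FALSE)
  }
  cl <- truth$cells; dr <- truth$droplets
  if (nrow(cl)) validate_in_bounds(cl$row, cl$col, cl$nucleus_radius)
  if (nrow(dr)) validate_in_bounds(dr$row, dr$col, dr$radius)
  nuc <- matrix(0, shape[1], shape[2])
  lip <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(cl)))
    nuc <- draw_disc(nuc, cl$row[i], cl$col[i], cl$nucleus_radius[i],
                     config$nucleus_amplitude)
  for (i in seq_len(nrow(dr)))
    lip <- draw_disc(lip, dr$row[i], dr$col[i], dr$radius[i],
                     dr$peak_intensity[i])
  nuc <- gaussian_blur(nuc, config$blur_sigma) + config$background_level
  lip <- gaussian_blur(lip, config$blur_sigma) + config$background_level
  add_noise <- function(x) {
    switch(config$noise_model,
      none = x,
      gaussian = x + rnorm(length(x), 0, config$noise_params$sd %||% 50),
      poisson_gaussian = {
        shot <- matrix(rpois(length(x), lambda = pmax(0, x)), nrow(x))
        shot + rnorm(length(x), 0, config$noise_params$sd %||% 10)
      })
  }
  maxval <- 2^config$bit_depth - 1
  finish <- function(x) {
    m <- matrix(as.integer(pmin(maxval, pmax(0, round(x)))), nrow(x))
    m
  }
  imgs <- with_seed(seed, list(nuclei = finish(add_noise(nuc)),
                               lipid = finish(add_noise(lip))))
  structure(c(imgs, list(field_id = truth$field_id, config = config)),
            class = "field_images")
}
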