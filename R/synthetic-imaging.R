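#' Specify the geometry and photometry of one synthetic yeast cell
#'
#' A cell is modelled as a nuclear-envelope (NE) fluorescent ring centred on
#' the nucleus, with an enriched arc facing the vacuole: the stand-in for a
#' GFP-tagged integral NE protein partitioned at the nucleus-vacuole junction
#' (NVJ). The arc centre is the point of the nuclear circle nearest the
#' vacuole centre, so the NVJ always lies on the nucleus-vacuole axis. With
#' \code{enrichment_factor = 1} the ring is rotationally uniform.
#'
#' @param nucleus_center numeric (x, y) in micrometres.
#' @param nucleus_radius nuclear-envelope radius in micrometres (> 0).
#' @param vacuole_center numeric (x, y) in micrometres.
#' @param vacuole_radius vacuole radius in micrometres (> 0).
#' @param nvj_arc_halfwidth angular half-width of the NVJ arc, radians in
#'   (0, pi/2]. The default pi/3 makes the junction span a third of the NE
#'   circumference, the visual scale of the contact in glucose-restricted
#'   cells.
#' @param enrichment_factor fold enrichment of ring intensity inside the NVJ
#'   arc relative to the rest of the NE (>= 1).
#' @param ne_ring_sigma radial Gaussian thickness of the NE signal,
#'   micrometres (> 0). The default 0.15 um corresponds to a
#'   diffraction-limited membrane cross-section (~0.35 um FWHM).
#' @param base_intensity expected photon count at the ring peak outside the
#'   NVJ arc, arbitrary units (> 0).
#' @param cytoplasm_intensity diffuse signal added inside the cell body disc
#'   (radius \code{1.8 * nucleus_radius}), arbitrary units (>= 0).
#' @return An object of class \code{cell_spec}.
#' @examples
#' spec <- cell_spec(nucleus_center = c(3.2, 3.2), vacuole_center = c(6, 3.2),
#'                   enrichment_factor = 15)
#' @export
cell_spec <- function(nucleus_center, nucleus_radius = 1.0,
                      vacuole_center, vacuole_radius = 1.5,
                      nvj_arc_halfwidth = pi / 3,
                      enrichment_factor = 1,
                      ne_ring_sigma = 0.15,
                      base_intensity = 2000,
                      cytoplasm_intensity = 50) {
  spec <- list(
    nucleus_center = check_point(nucleus_center, "nucleus_center"),
    nucleus_radius = check_number(nucleus_radius, "nucleus_radius",
                                  lower = 0, strict_lower = TRUE),
    vacuole_center = check_point(vacuole_center, "vacuole_center"),
    vacuole_radius = check_number(vacuole_radius, "vacuole_radius",
                                  lower = 0, strict_lower = TRUE),
    nvj_arc_halfwidth = check_number(nvj_arc_halfwidth, "nvj_arc_halfwidth",
                                     lower = 0, upper = pi / 2,
                                     strict_lower = TRUE),
    enrichment_factor = check_number(enrichment_factor, "enrichment_factor",
                                     lower = 1),
    ne_ring_sigma = check_number(ne_ring_sigma, "ne_ring_sigma",
                                 lower = 0, strict_lower = TRUE),
    base_intensity = check_number(base_intensity, "base_intensity",
                                  lower = 0, strict_lower = TRUE),
    cytoplasm_intensity = check_number(cytoplasm_intensity,
                                       "cytoplasm_intensity", lower = 0)
  )
  if (sqrt(sum((spec$vacuole_center - spec$nucleus_center)^2)) <= 0) {
    stop("vacuole_center must differ from nucleus_center ",
         "(the NVJ direction would be undefined)", call. = FALSE)
  }
  class(spec) <- "cell_spec"
  spec
}

#' Imaging configuration for the synthetic renderer
#'
#' @param pixel_size micrometres per pixel (> 0).
#' @param image_shape integer (rows, cols) of the rendered image.
#' @param psf_sigma standard deviation of the isotropic Gaussian point-spread
#'   function, micrometres (>= 0; 0 disables blurring).
#' @param poisson_noise simulate photon shot noise (Poisson on expected
#'   counts)?
#' @param read_noise_sigma standard deviation of additive Gaussian camera
#'   read noise, arbitrary units (>= 0).
#' @param bit_depth camera bit depth; output values are clipped and
#'   quantized to \code{[0, 2^bit_depth - 1]}.
#' @param rng_seed integer seed; rendering with identical spec, config and
#'   seed is bit-identical.
#' @return An object of class \code{imaging_config}.
#' @export
imaging_config <- function(pixel_size = 0.1, image_shape = c(64L, 64L),
                           psf_sigma = 0.1, poisson_noise = TRUE,
                           read_noise_sigma = 10, bit_depth = 16L,
                           rng_seed = 1L) {
  if (!is.numeric(image_shape) || length(image_shape) != 2L ||
      any(image_shape < 8)) {
    stop("'image_shape' must be (rows, cols) with both >= 8", call. = FALSE)
  }
  cfg <- list(
    pixel_size = check_number(pixel_size, "pixel_size",
                              lower = 0, strict_lower = TRUE),
    image_shape = as.integer(image_shape),
    psf_sigma = check_number(psf_sigma, "psf_sigma", lower = 0),
    poisson_noise = check_flag(poisson_noise, "poisson_noise"),
    read_noise_sigma = check_number(read_noise_sigma, "read_noise_sigma",
                                    lower = 0),
    bit_depth = as.integer(check_number(bit_depth, "bit_depth",
                                        lower = 8, upper = 16)),
    rng_seed = as.integer(check_number(rng_seed, "rng_seed",
                                       lower = -2^31, upper = 2^31 - 1))
  )
  class(cfg) <- "imaging_config"
  cfg
}

# angle (radians) from nucleus centre towards the vacuole centre:
# the centre of the NVJ arc
nvj_angle <- function(spec) {
  d <- spec$vacuole_center - spec$nucleus_center
  atan2(d[2], d[1])
}

# angular amplitude of the NE ring: base outside the NVJ arc,
# enrichment_factor * base inside (top-hat arc profile)
ring_amplitude <- function(spec, theta) {
  inside <- abs(ang_diff(theta, nvj_angle(spec))) <= spec$nvj_arc_halfwidth
  spec$base_intensity * ifelse(inside, spec$enrichment_factor, 1)
}

# noise-free, PSF-free expected ring-channel image of one cell
render_ring_analytic <- function(spec, cfg) {
  ps <- cfg$pixel_size
  rows <- cfg$image_shape[1]
  cols <- cfg$image_shape[2]
  # physical coordinates of pixel centres: x = col * pixel_size (0-based)
  x <- matrix(rep((seq_len(cols) - 1) * ps, each = rows), rows, cols)
  y <- matrix(rep((seq_len(rows) - 1) * ps, times = cols), rows, cols)
  dx <- x - spec$nucleus_center[1]
  dy <- y - spec$nucleus_center[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  amp <- matrix(ring_amplitude(spec, as.vector(theta)), rows, cols)
  img <- amp * exp(-(r - spec$nucleus_radius)^2 / (2 * spec$ne_ring_sigma^2))
  # diffuse cell-body signal (cytoplasm + nucleoplasm stand-in)
  img + spec$cytoplasm_intensity * (r <= 1.8 * spec$nucleus_radius)
}

# vacuole-marker channel (FM4-64 stand-in): filled disc, never used by
# quantification
render_vacuole_analytic <- function(spec, cfg) {
  ps <- cfg$pixel_size
  rows <- cfg$image_shape[1]
  cols <- cfg$image_shape[2]
  x <- matrix(rep((seq_len(cols) - 1) * ps, each = rows), rows, cols)
  y <- matrix(rep((seq_len(rows) - 1) * ps, times = cols), rows, cols)
  r <- sqrt((x - spec$vacuole_center[1])^2 + (y - spec$vacuole_center[2])^2)
  0.5 * spec$base_intensity * (r <= spec$vacuole_radius)
}

apply_psf <- function(img, cfg) {
  if (cfg$psf_sigma <= 0) return(img)
  sigma_px <- cfg$psf_sigma / cfg$pixel_size
  EBImage::gblur(img, sigma = sigma_px, boundary = "replicate")
}

# Poisson shot noise + Gaussian read noise, clip and quantize to the camera
# bit depth. Caller is responsible for seeding.
apply_camera <- function(img, cfg) {
  v <- as.vector(img)
  if (cfg$poisson_noise) v <- rpois(length(v), pmax(v, 0))
  if (cfg$read_noise_sigma > 0) v <- v + rnorm(length(v), 0,
                                               cfg$read_noise_sigma)
  maxval <- 2^cfg$bit_depth - 1
  matrix(round(pmin(pmax(v, 0), maxval)), nrow(img), ncol(img))
}

# endpoints (2x2 matrix, rows = points, columns = x/y in um) of a radial
# scan line of length `len` centred on the NE crossing at angle `theta`
radial_scanline <- function(spec, theta, len) {
  u <- c(cos(theta), sin(theta))
  p0 <- spec$nucleus_center + (spec$nucleus_radius - len / 2) * u
  p1 <- spec$nucleus_center + (spec$nucleus_radius + len / 2) * u
  rbind(p0, p1, deparse.level = 0)
}

check_cell_in_bounds <- function(spec, cfg, pad) {
  ps <- cfg$pixel_size
  lim <- (cfg$image_shape[c(2, 1)] - 1) * ps  # (x_max, y_max)
  reach <- spec$nucleus_radius + pad
  for (axis in 1:2) {
    nm <- c("x", "y")[axis]
    if (spec$nucleus_center[axis] - reach < 0 ||
        spec$nucleus_center[axis] + reach > lim[axis]) {
      stop(sprintf(
        "cell does not fit in the image: nucleus %s = %g um with reach %g um exceeds [0, %g]",
        nm, spec$nucleus_center[axis], reach, lim[axis]
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

new_synthetic_image <- function(ring, vacuole, cfg, truth) {
  attr(ring, "pixel_size") <- cfg$pixel_size
  attr(vacuole, "pixel_size") <- cfg$pixel_size
  structure(list(ring = ring, vacuole = vacuole,
                 pixel_size = cfg$pixel_size, truth = truth, config = cfg),
            class = "synthetic_image")
}

cell_truth <- function(spec, scan_length) {
  th <- nvj_angle(spec)
  list(
    nucleus_center = spec$nucleus_center,
    nucleus_radius = spec$nucleus_radius,
    enrichment = spec$enrichment_factor,
    theta_nvj = th,
    scanline_nvj = radial_scanline(spec, th, scan_length),
    scanline_opposite = radial_scanline(spec, th + pi, scan_length)
  )
}

#' Render one synthetic two-channel cell image
#'
#' Channel 1 carries the NE ring whose angular profile is
#' \code{base_intensity} outside the NVJ arc and
#' \code{enrichment_factor * base_intensity} inside it, modulated radially by
#' a Gaussian of width \code{ne_ring_sigma}, convolved with the PSF and
#' degraded by camera noise. Channel 2 is a filled vacuole disc. The ground
#' truth records the arc geometry and the two radial scan lines (NVJ-side and
#' antipodal NE crossing) needed by the partitioning quantification.
#'
#' @param spec a \code{\link{cell_spec}}.
#' @param cfg an \code{\link{imaging_config}}.
#' @param scan_length length of the ground-truth scan lines, micrometres.
#' @return A \code{synthetic_image}: list with \code{ring} and \code{vacuole}
#'   matrices (pixel values in \code{[0, 2^bit_depth - 1]}, pixel size
#'   attached as an attribute), and \code{truth}, a one-element list of
#'   per-cell ground-truth records.
#' @export
render_cell <- function(spec, cfg = imaging_config(), scan_length = 1.5) {
  stopifnot(inherits(spec, "cell_spec"), inherits(cfg, "imaging_config"))
  check_cell_in_bounds(spec, cfg,
                       pad = max(3 * spec$ne_ring_sigma, scan_length / 2))
  ring <- apply_psf(render_ring_analytic(spec, cfg), cfg)
  vac <- apply_psf(render_vacuole_analytic(spec, cfg), cfg)
  out <- with_seed(cfg$rng_seed, {
    list(ring = apply_camera(ring, cfg), vacuole = apply_camera(vac, cfg))
  })
  new_synthetic_image(out$ring, out$vacuole, cfg,
                      truth = list(cell_truth(spec, scan_length)))
}

#' Render a field of view containing several cells
#'
#' Cells are validated to be non-overlapping (pairwise centre distance must
#' exceed the sum of nuclear radii plus \code{margin}); their analytic images
#' are summed before a single PSF/noise pass. The returned ground-truth table
#' has one row per cell with its true enrichment and scan-line endpoints, the
#' input a blind end-to-end test of the partitioning pipeline needs.
#'
#' @param specs non-empty list of \code{\link{cell_spec}} objects.
#' @param cfg an \code{\link{imaging_config}}.
#' @param scan_length ground-truth scan-line length, micrometres.
#' @param margin minimum clearance between nuclear circles, micrometres.
#' @return A \code{synthetic_image} whose \code{truth} holds one record per
#'   cell. Use \code{\link{truth_table}} for a data-frame view.
#' @export
render_field <- function(specs, cfg = imaging_config(), scan_length = 1.5,
                         margin = 1.0) {
  if (!is.list(specs) || length(specs) == 0L ||
      !all(vapply(specs, inherits, logical(1), "cell_spec"))) {
    stop("'specs' must be a non-empty list of cell_spec objects",
         call. = FALSE)
  }
  n <- length(specs)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum((specs[[i]]$nucleus_center -
                         specs[[j]]$nucleus_center)^2))
        need <- specs[[i]]$nucleus_radius + specs[[j]]$nucleus_radius + margin
        if (d <= need) {
          stop(sprintf(
            "cells %d and %d overlap: centre distance %.3g um <= %.3g um required",
            i, j, d, need
          ), call. = FALSE)
        }
      }
    }
  }
  pad <- max(vapply(specs, function(s) 3 * s$ne_ring_sigma, numeric(1)),
             scan_length / 2)
  for (s in specs) check_cell_in_bounds(s, cfg, pad)
  ring <- Reduce(`+`, lapply(specs, render_ring_analytic, cfg = cfg))
  vac <- Reduce(`+`, lapply(specs, render_vacuole_analytic, cfg = cfg))
  ring <- apply_psf(ring, cfg)
  vac <- apply_psf(vac, cfg)
  out <- with_seed(cfg$rng_seed, {
    list(ring = apply_camera(ring, cfg), vacuole = apply_camera(vac, cfg))
  })
  new_synthetic_image(out$ring, out$vacuole, cfg,
                      truth = lapply(specs, cell_truth, scan_length))
}

#' Ground truth of a synthetic image as a data frame
#'
#' @param img a \code{synthetic_image}.
#' @return A data frame with one row per cell: centre, radius, enrichment,
#'   an \code{enriched} flag (enrichment > 1) and the scan-line endpoints in
#'   micrometres.
#' @export
truth_table <- function(img) {
  stopifnot(inherits(img, "synthetic_image"))
  rows <- lapply(seq_along(img$truth), function(i) {
    tr <- img$truth[[i]]
    data.frame(
      cell_id = i,
      center_x = tr$nucleus_center[1], center_y = tr$nucleus_center[2],
      nucleus_radius = tr$nucleus_radius,
      enrichment = tr$enrichment,
      enriched = tr$enrichment > 1,
      nvj_x0 = tr$scanline_nvj[1, 1], nvj_y0 = tr$scanline_nvj[1, 2],
      nvj_x1 = tr$scanline_nvj[2, 1], nvj_y1 = tr$scanline_nvj[2, 2],
      opp_x0 = tr$scanline_opposite[1, 1], opp_y0 = tr$scanline_opposite[1, 2],
      opp_x1 = tr$scanline_opposite[2, 1], opp_y1 = tr$scanline_opposite[2, 2]
    )
  })
  do.call(rbind, rows)
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf(
    "synthetic_image: %d x %d px (%.3g um/px), %d cell(s)\n",
    nrow(x$ring), ncol(x$ring), x$pixel_size, length(x$truth)
  ))
  invisible(x)
}
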