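test_that("enrichment_factor = 1 gives a rotationally uniform ring", {
  cfg <- quiet_config(psf_sigma = 0)
  east <- render_cell(cell_spec(nucleus_center = c(3.2, 3.2),
                                vacuole_center = c(5.5, 3.2)), cfg)
  north <- render_cell(cell_spec(nucleus_center = c(3.2, 3.2),
                                 vacuole_center = c(3.2, 5.5)), cfg)
  # no privileged arc: the rendered ring cannot depend on the vacuole side
  expect_identical(east$ring, north$ring)
})

test_that("rendered arc-mean ratio matches the specified enrichment", {
  spec <- symmetric_cell(enrichment = 15, cytoplasm_intensity = 0)
  cfg <- quiet_config(psf_sigma = 0.1)  # psf_sigma < ne_ring_sigma
  img <- render_cell(spec, cfg)
  # sample ring-peak pixels well inside each arc (clear of PSF-smeared edges)
  ps <- cfg$pixel_size
  x <- outer(rep(1, nrow(img$ring)), (seq_len(ncol(img$ring)) - 1) * ps)
  y <- outer((seq_len(nrow(img$ring)) - 1) * ps, rep(1, ncol(img$ring)))
  dx <- x - spec$nucleus_center[1]
  dy <- y - spec$nucleus_center[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  on_ring <- abs(r - spec$nucleus_radius) < spec$ne_ring_sigma / 2
  margin <- 3 * cfg$psf_sigma / spec$nucleus_radius
  in_nvj <- abs(th) < spec$nvj_arc_halfwidth - margin
  in_opp <- abs(abs(th) - pi) < spec$nvj_arc_halfwidth - margin
  ratio <- mean(img$ring[on_ring & in_nvj]) / mean(img$ring[on_ring & in_opp])
  expect_equal(ratio, 15, tolerance = 0.02)
})

test_that("rendering is deterministic in the seed", {
  spec <- symmetric_cell(enrichment = 10)
  a <- render_cell(spec, imaging_config(rng_seed = 42))
  b <- render_cell(spec, imaging_config(rng_seed = 42))
  c <- render_cell(spec, imaging_config(rng_seed = 43))
  expect_identical(a$ring, b$ring)
  expect_identical(a$vacuole, b$vacuole)
  expect_false(identical(a$ring, c$ring))
  expect_true(all(a$ring >= 0 & a$ring <= 2^16 - 1))
})

test_that("invalid geometry and parameters are rejected with clear errors", {
  expect_error(cell_spec(nucleus_center = c(3, 3), vacuole_center = c(5, 3),
                         enrichment_factor = 0.5), "enrichment_factor")
  expect_error(
    render_cell(cell_spec(nucleus_center = c(0.5, 3.2),
                          vacuole_center = c(2, 3.2)), quiet_config()),
    "nucleus x"
  )
  expect_error(
    render_cell(cell_spec(nucleus_center = c(3.2, 6.2),
                          vacuole_center = c(3.2, 4)), quiet_config()),
    "nucleus y"
  )
  expect_error(cell_spec(nucleus_center = c(3, 3), vacuole_center = c(3, 3)),
               "NVJ direction")
})

test_that("field rendering keeps per-cell ground truth and rejects overlap", {
  cfg <- imaging_config(image_shape = c(64, 230), rng_seed = 5)
  specs <- lapply(1:10, function(i) {
    cell_spec(nucleus_center = c(1.0 + 1.9 * i, 3.2),
              vacuole_center = c(1.0 + 1.9 * i, 5.4),
              vacuole_radius = 0.8,
              enrichment_factor = if (i <= 3) 10 else 1)
  })
  fld <- render_field(specs, cfg, margin = -0.5)
  tt <- truth_table(fld)
  expect_equal(nrow(tt), 10)
  expect_equal(sum(tt$enriched), 3)
  # same seed, same field
  fld2 <- render_field(specs, cfg, margin = -0.5)
  expect_identical(fld$ring, fld2$ring)
  expect_error(render_field(list(), cfg), "non-empty")
  expect_error(render_field(specs, cfg, margin = 1.0), "cells 1 and 2")
})

test_that("noise-free cell fluorescence is linear in base_intensity", {
  cfg <- quiet_config()
  mk <- function(base) {
    render_cell(symmetric_cell(enrichment = 5, base_intensity = base,
                               cytoplasm_intensity = 0), cfg)$ring
  }
  expect_equal(sum(mk(3000)), 3 * sum(mk(1000)), tolerance = 1e-3)
})

test_that("rasterized arc-mean ratio converges with finer pixels", {
  # the NVJ-arc mask is mirrored through the symmetry axis to sample the
  # antipodal arc at exactly matched pixels
  arc_ratio <- function(ps) {
    spec <- symmetric_cell(enrichment = 10, cytoplasm_intensity = 0)
    cfg <- quiet_config(pixel_size = ps, psf_sigma = 0,
                        image_shape = round(c(64, 64) * 0.1 / ps))
    img <- render_cell(spec, cfg)
    nr <- nrow(img$ring)
    nc <- ncol(img$ring)
    x <- outer(rep(1, nr), (seq_len(nc) - 1) * ps)
    y <- outer((seq_len(nr) - 1) * ps, rep(1, nc))
    dx <- x - spec$nucleus_center[1]
    dy <- y - spec$nucleus_center[2]
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    idx <- which(abs(r - spec$nucleus_radius) < spec$ne_ring_sigma &
                   abs(th) < spec$nvj_arc_halfwidth * 0.8, arr.ind = TRUE)
    mir <- cbind(idx[, 1],
                 round(2 * spec$nucleus_center[1] / ps) - idx[, 2] + 2)
    mean(img$ring[idx]) / mean(img$ring[mir])
  }
  err <- abs(c(arc_ratio(0.1), arc_ratio(0.025)) - 10)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 1e-3)
})
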