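test_that("default protocols encode the published acquisition schedules", {
  p <- default_protocols()
  expect_equal(nrow(p$flip$bleach_events), 50)
  expect_equal(max(p$flip$frame_times) - min(p$flip$frame_times), 300)
  expect_equal(unique(diff(p$frap$frame_times)), 0.5)
  expect_equal(max(p$frap$frame_times) - min(p$frap$frame_times), 25)
  # one pre-bleach frame, then 50 post-bleach frames
  expect_equal(sum(p$frap$frame_times > p$frap$bleach_events$time[1]), 50)
  expect_equal(nrow(p$frap$bleach_events), 1)
  expect_equal(p$frap$roi_area_label, 0.77)
})

test_that("total ring signal is conserved without bleaching", {
  proto <- make_protocol("frap", frame_times = seq(0, 40, 2),
                         bleach_events = no_bleach_events(),
                         rois = nvjquant:::default_rois(2 * pi, 1))
  sim <- simulate_photobleach(ring_params(k_on = 0.2, k_off = 0.05), proto)
  whole <- sim$signals[, "whole"]
  expect_lt(max(abs(whole / whole[1] - 1)), 1e-9)
})

test_that("the bound/free pools relax to the k_on/k_off steady state", {
  k_on <- 1
  k_off <- 0.5
  C <- 2 * pi
  span <- 1.0
  w <- nvjquant:::roi_arc_width()
  proto <- make_protocol("frap", frame_times = seq(0, 60, 2),
                         bleach_events = no_bleach_events(),
                         rois = nvjquant:::default_rois(C, w))
  sim <- simulate_photobleach(ring_params(k_on = k_on, k_off = k_off),
                              proto, start_equilibrium = FALSE)
  # at equilibrium the free density is uniform and the NVJ carries an extra
  # bound pool of k_on/k_off times the local free amount
  r <- k_on / k_off
  rho_f <- C / (C + r * span)
  predicted <- rho_f * w * (1 + r)
  expect_equal(tail(sim$traces$nvj$roi, 1), predicted, tolerance = 0.01)
  # and the signal away from the NVJ holds only the free pool
  expect_equal(tail(sim$traces$opposite_ne$roi, 1), rho_f * w,
               tolerance = 0.01)
})

test_that("a stability-violating time step is rejected with a suggestion", {
  p <- ring_params()
  dt_max <- 0.5 * (p$circumference / p$n_sites)^2 / p$D
  expect_error(simulate_photobleach(p, protocol_frap(), dt = 2 * dt_max),
               "stability")
  expect_error(simulate_photobleach(p, protocol_frap(), dt = 2 * dt_max),
               "use dt <=")
})

test_that("pure diffusion under FLIP is symmetric about the bleach ROI", {
  C <- 2 * pi
  w <- nvjquant:::roi_arc_width()
  rois <- list(nvj = c(C / 4 - w / 2, C / 4 + w / 2),
               mirror = c(3 * C / 4 - w / 2, 3 * C / 4 + w / 2),
               opposite_ne = c(C / 2 - w / 2, C / 2 + w / 2),
               whole = c(0, C))
  base <- protocol_flip(C)
  proto <- make_protocol("flip", base$frame_times, base$bleach_events, rois)
  sim <- simulate_photobleach(ring_params(k_on = 0), proto)
  ht <- vapply(c("nvj", "mirror"), function(nm) {
    fit_normalized(flip_normalize(sim$traces[[nm]]))$halftime
  }, numeric(1))
  expect_equal(ht[["nvj"]], ht[["mirror"]], tolerance = 0.03)
})

test_that("slower release prolongs the fitted NVJ halftime monotonically", {
  ht <- vapply(c(1, 0.1, 0.01), function(k_off) {
    sim <- simulate_photobleach(ring_params(k_on = 0.1, k_off = k_off),
                                protocol_flip())
    fit_normalized(flip_normalize(sim$traces$nvj))$halftime
  }, numeric(1))
  expect_true(all(diff(ht) > 0))
})

test_that("FLIP loss curves never rise meaningfully above their pre-bleach level", {
  sim <- simulate_photobleach(demo_ring_params(TRUE), protocol_flip())
  v <- flip_normalize(sim$traces$nvj)$values
  expect_lt(max(v), 1 + 1e-9)
})

test_that("grid refinement leaves the ROI traces essentially unchanged", {
  base <- protocol_flip()
  short <- make_protocol("flip",
                         base$frame_times[base$frame_times <= 60],
                         base$bleach_events[base$bleach_events$time <= 60, ],
                         base$roi_definitions)
  tr <- lapply(c(128, 256), function(n) {
    p <- demo_ring_params(TRUE)
    p$n_sites <- as.integer(n)
    simulate_photobleach(p, short)$signals
  })
  rel <- max(abs(tr[[1]] - tr[[2]])) / max(abs(tr[[2]]))
  expect_lt(rel, 0.01)
})

test_that("the retention demo orders bound and free halftimes correctly", {
  demo <- calibrate_demo()
  expect_true(demo$ordering_ok)
  expect_true(demo$retained_gt_100)
  expect_true(demo$free_near_25)
  # identical parameter sets give identical fitted halftimes
  same <- calibrate_demo(demo_ring_params(FALSE), demo_ring_params(FALSE))
  expect_equal(same$halftime_retained, same$halftime_free, tolerance = 1e-10)
  # in the fast-release limit binding cannot retain: halftime approaches
  # the no-binding value
  fast <- ring_params(k_on = 0.1, k_off = 1000)
  lim <- calibrate_demo(fast, demo_ring_params(FALSE))
  expect_equal(lim$halftime_retained, lim$halftime_free, tolerance = 0.05)
})

test_that("the FRAP recovery of a free ring matches the analytic diffusion solution", {
  C <- 6.4
  n <- 128L
  w <- 1.0
  s <- 0.1
  D <- 0.3
  # ROI bounds are multiples of dx so the discrete top-hat is exact
  rois <- list(nvj = c(-w / 2, w / 2),
               opposite_ne = c(C / 2 - w / 2, C / 2 + w / 2),
               whole = c(0, C))
  proto <- make_protocol("frap", frame_times = seq(0, 25, 0.5),
                         bleach_events = data.frame(time = 0.25, roi = "nvj",
                                                    survival = s),
                         rois = rois)
  sim <- simulate_photobleach(ring_params(circumference = C, n_sites = n,
                                          D = D, nvj_span = 0, k_on = 0),
                              proto)
  tr <- sim$traces$nvj
  post <- tr$times > 0.25
  oracle <- ring_fourier_roi(C, D, -w / 2, w / 2, s, tr$times[post] - 0.25)
  expect_lt(max(abs(tr$roi[post] - oracle) / abs(oracle)), 0.01)
})
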