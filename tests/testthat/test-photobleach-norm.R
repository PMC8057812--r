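test_that("double normalization reproduces the hand-computed example", {
  tr <- intensity_trace(times = c(0, 1, 2), roi = c(100, 20, 60),
                        whole_cell = c(1000, 900, 900),
                        pre_index = 1, bleach_index = 2)
  nd <- frap_double_normalize(tr)
  expect_equal(nd$values, c(1.0, (1000 / 900) * 0.2, (1000 / 900) * 0.6),
               tolerance = 1e-12)
  expect_equal(nd$values, c(1.0, 0.2222, 0.6667), tolerance = 1e-4)
  full <- frap_full_normalize(nd)
  expect_equal(full$values, c(1.0, 0.0, 0.5714), tolerance = 1e-4)
})

test_that("normalization endpoint identities hold for arbitrary valid traces", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    tr <- intensity_trace(
      times = cumsum(runif(n, 0.2, 1)),
      roi = runif(n, 10, 200),
      whole_cell = runif(n, 500, 1500),
      pre_index = 1, bleach_index = sample(2:5, 1)
    )
    nd <- frap_double_normalize(tr)
    expect_identical(nd$values[nd$pre_index], 1.0)
    full <- frap_full_normalize(nd)
    expect_equal(full$values[full$pre_index], 1.0, tolerance = 1e-14)
    expect_equal(full$values[full$bleach_index], 0.0, tolerance = 1e-14)
    # re-applying the pre/bleach rescaling must change nothing
    again <- (full$values - full$values[full$bleach_index]) /
      (full$values[full$pre_index] - full$values[full$bleach_index])
    expect_equal(again, full$values, tolerance = 1e-12)
  }
})

test_that("double normalization reduces and rescales as expected", {
  tt <- c(0, 1, 2, 3)
  # constant whole-cell: Eq-style correction factor is 1
  tr <- intensity_trace(tt, roi = c(80, 10, 30, 60),
                        whole_cell = rep(900, 4))
  expect_equal(frap_double_normalize(tr)$values, c(80, 10, 30, 60) / 80)
  # common rescaling of roi and whole-cell leaves the output unchanged
  tr2 <- intensity_trace(tt, roi = 3.1 * c(80, 10, 30, 60),
                         whole_cell = 3.1 * rep(900, 4))
  expect_equal(frap_double_normalize(tr2)$values,
               frap_double_normalize(tr)$values, tolerance = 1e-12)
  # full recovery back to the pre-bleach level ends at exactly 1
  tr3 <- intensity_trace(tt, roi = c(100, 10, 60, 100),
                         whole_cell = rep(1000, 4))
  expect_equal(tail(frap_full_normalize(tr3)$values, 1), 1.0)
  expect_error(frap_full_normalize(
    intensity_trace(tt, roi = rep(50, 4), whole_cell = rep(1000, 4))
  ), "bleach depth")
})

test_that("FLIP normalization divides by the pre-bleach value", {
  tr <- intensity_trace(c(0, 1, 2), roi = c(200, 150, 100),
                        pre_index = 1, bleach_index = 2)
  expect_equal(flip_normalize(tr)$values, c(1, 0.75, 0.5))
  const <- intensity_trace(c(0, 1, 2), roi = rep(42, 3))
  expect_equal(flip_normalize(const)$values, rep(1, 3))
  zero <- intensity_trace(c(0, 1, 2), roi = c(0, 5, 5))
  expect_error(flip_normalize(zero), "pre-bleach")
})

test_that("one-phase fits recover noise-free rates to machine-level accuracy", {
  tt <- seq(0, 25, 0.5)
  fa <- fit_one_phase(tt, 0.8 * (1 - exp(-0.34657 * tt)), "association")
  expect_true(fa$converged)
  expect_equal(fa$halftime, log(2) / 0.34657, tolerance = 1e-6)
  expect_equal(fa$amplitude, 0.8, tolerance = 1e-6)
  td <- seq(0, 300, 6)
  fd <- fit_one_phase(td, exp(-0.027726 * td), "decay")
  expect_true(fd$converged)
  expect_equal(fd$halftime, 25.0, tolerance = 1e-5)
  expect_equal(fd$halftime * fd$rate_k, log(2))
})

test_that("halving the sampling rate barely moves a noise-free halftime", {
  tt <- seq(0, 25, 0.5)
  y <- 0.75 * (1 - exp(-0.4 * tt))
  full <- fit_one_phase(tt, y, "association")$halftime
  sub <- fit_one_phase(tt[c(TRUE, FALSE)], y[c(TRUE, FALSE)],
                       "association")$halftime
  expect_equal(sub, full, tolerance = 0.02)
})

test_that("hopeless fits are flagged, never silently reported", {
  # decay model on rising data pins the rate at its lower bound
  f <- fit_one_phase(seq(0, 10, 0.5), seq(0.1, 1, length.out = 21), "decay")
  expect_false(f$converged)
  expect_error(fit_one_phase(c(0, 1, 2), c(1, 2, 3), "decay"), ">= 5")
})

test_that("fit_normalized uses the bleach frame as its time origin", {
  tt <- seq(0, 25, 0.5)
  k <- 0.5
  roi <- c(100, 100 * (1e-6 + 0.7 * (1 - exp(-k * (tt[-1] - tt[2])))))
  tr <- intensity_trace(tt, roi, whole_cell = rep(1000, length(tt)))
  fit <- fit_normalized(frap_full_normalize(tr))
  expect_true(fit$converged)
  expect_equal(fit$rate_k, k, tolerance = 1e-4)
})

test_that("halftime summaries exclude non-converged fits per group", {
  mk <- function(ht, ok = TRUE) {
    structure(list(kind = "decay", rate_k = log(2) / ht, halftime = ht,
                   amplitude = 1, offset = 0, rmse = 0, converged = ok,
                   n = 10), class = "exp_fit")
  }
  fits <- list(mk(1), mk(2), mk(3), mk(50, ok = FALSE), mk(100), mk(120))
  s <- halftime_summary(fits, c("a", "a", "a", "a", "b", "b"))
  sa <- s[s$group == "a", ]
  expect_equal(sa$n, 3)
  expect_equal(sa$excluded, 1)
  expect_equal(sa$median_halftime, 2)
  # ordering of true group halftimes survives summarization
  expect_lt(sa$median_halftime, s[s$group == "b", "median_halftime"])
  expect_error(halftime_summary(list(mk(1, ok = FALSE))), "no converged")
})
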