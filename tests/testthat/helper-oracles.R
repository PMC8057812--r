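# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive results by brute force or closed form and
# never call the code paths they are used to check.

# Direct spatial-domain Gaussian convolution with replicate padding, the
# oracle for the blur used in background subtraction. Kernel size matches
# the 2*ceiling(3*sigma)+1 support convention.
conv_gauss_oracle <- function(img, sigma) {
  size <- 2 * ceiling(3 * sigma) + 1
  h <- (size - 1) / 2
  g <- outer(-h:h, -h:h, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  g <- g / sum(g)
  nr <- nrow(img)
  nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    rr <- pmin(pmax(r + (-h:h), 1), nr)
    for (c in seq_len(nc)) {
      cc <- pmin(pmax(c + (-h:h), 1), nc)
      out[r, c] <- sum(g * img[rr, cc])
    }
  }
  out
}

# Brute-force two-sample KS statistic: evaluate both ECDFs at every pooled
# observation and take the largest gap.
ks_brute_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(fa - fb))
}

# Analytic Fourier-mode solution for pure diffusion on a ring after an
# instantaneous partial bleach of the interval [a, b] (survival s): returns
# the [a, b]-integrated signal at the requested post-bleach times.
ring_fourier_roi <- function(C, D, a, b, s, t_post, n_modes = 400) {
  w <- b - a
  vapply(t_post, function(t) {
    tot <- (C - (1 - s) * w) / C * w
    m <- seq_len(n_modes)
    k <- 2 * pi * m / C
    cm <- -(1 - s) / C * (exp(-1i * k * a) - exp(-1i * k * b)) / (1i * k)
    Im <- (exp(1i * k * b) - exp(1i * k * a)) / (1i * k)
    tot + sum(2 * Re(cm * Im) * exp(-D * k^2 * t))
  }, numeric(1))
}

# Standard single-cell geometry: nucleus centred on a grid-symmetric point
# with the vacuole due east, so the NVJ and antipodal scan lines are
# mirror images on the pixel grid.
symmetric_cell <- function(enrichment = 1, ...) {
  cell_spec(nucleus_center = c(3.2, 3.2), vacuole_center = c(5.5, 3.2),
            enrichment_factor = enrichment, ...)
}

quiet_config <- function(...) {
  imaging_config(poisson_noise = FALSE, read_noise_sigma = 0, ...)
}

# A bleach protocol built directly (bypassing the exported constructors)
# for tests that need custom schedules or ROI layouts.
make_protocol <- function(kind, frame_times, bleach_events, rois) {
  nvjquant:::new_protocol(kind, frame_times, bleach_events, rois)
}

no_bleach_events <- function() {
  data.frame(time = numeric(0), roi = character(0), survival = numeric(0))
}

# a valid, curvy FRAP-style raw trace used by the normalization tests
example_frap_trace <- function() {
  tt <- seq(0, 25, 0.5)
  roi <- c(100, 20, 20 + 60 * (1 - exp(-0.3 * (tt[-(1:2)] - 0.5))))
  wc <- 1000 - 8 * seq_along(tt)
  intensity_trace(tt, roi, wc, pre_index = 1, bleach_index = 2)
}
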