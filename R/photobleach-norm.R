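#' Construct a photobleaching intensity trace
#'
#' Holds the raw per-frame intensities of a FRAP or FLIP movie: the
#' monitored ROI (the bleached region for FRAP, the NVJ for FLIP), the
#' whole-cell signal used by double normalization, and the indices of the
#' pre-bleach frame and of the frame at/immediately after the (first)
#' bleach. Indices are 1-based.
#'
#' @param times frame acquisition times in seconds, strictly increasing.
#' @param roi ROI intensity per frame, arbitrary units (>= 0).
#' @param whole_cell whole-cell intensity per frame; optional (FLIP
#'   normalization does not use it).
#' @param pre_index index of the pre-bleach frame.
#' @param bleach_index index of the first post-bleach frame;
#'   must exceed \code{pre_index}.
#' @return An object of class \code{intensity_trace}.
#' @export
intensity_trace <- function(times, roi, whole_cell = NULL,
                            pre_index = 1L, bleach_index = 2L) {
  times <- as.numeric(times)
  roi <- as.numeric(roi)
  n <- length(times)
  if (n < 2 || any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing with >= 2 frames",
         call. = FALSE)
  }
  if (length(roi) != n) stop("'roi' length must match 'times'", call. = FALSE)
  if (any(!is.finite(roi)) || any(roi < 0)) {
    stop("'roi' intensities must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(whole_cell)) {
    whole_cell <- as.numeric(whole_cell)
    if (length(whole_cell) != n) {
      stop("'whole_cell' length must match 'times'", call. = FALSE)
    }
    if (any(!is.finite(whole_cell)) || any(whole_cell < 0)) {
      stop("'whole_cell' intensities must be finite and >= 0", call. = FALSE)
    }
  }
  pre_index <- as.integer(pre_index)
  bleach_index <- as.integer(bleach_index)
  if (pre_index < 1L || bleach_index > n || pre_index >= bleach_index) {
    stop("need 1 <= pre_index < bleach_index <= number of frames",
         call. = FALSE)
  }
  structure(list(times = times, roi = roi, whole_cell = whole_cell,
                 pre_index = pre_index, bleach_index = bleach_index),
            class = "intensity_trace")
}

new_normalized_trace <- function(trace, values, kind) {
  structure(list(times = trace$times, values = values, kind = kind,
                 pre_index = trace$pre_index,
                 bleach_index = trace$bleach_index),
            class = "normalized_trace")
}

#' Double normalization of a FRAP trace
#'
#' Corrects the ROI recovery for the fluorescence lost to the bleach pulse
#' and to acquisition photobleaching, using the whole-cell signal:
#' \deqn{I_{norm}(t) = \frac{I_{whole-cell,pre}}{I_{whole-cell}(t)} \cdot
#'       \frac{I_{frap}(t)}{I_{frap,pre}}}
#' so the pre-bleach frame maps to exactly 1.
#'
#' @param trace an \code{\link{intensity_trace}} with \code{whole_cell}.
#' @return A \code{normalized_trace} of kind \code{"frap_double"}.
#' @export
frap_double_normalize <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (is.null(trace$whole_cell)) {
    stop("double normalization needs the whole-cell trace", call. = FALSE)
  }
  if (trace$roi[trace$pre_index] <= 0) {
    stop(sprintf("ROI intensity at the pre-bleach frame (%d) is not > 0",
                 trace$pre_index), call. = FALSE)
  }
  bad <- which(trace$whole_cell <= 0)
  if (length(bad) > 0) {
    stop(sprintf("whole-cell intensity is zero at frame(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  v <- (trace$whole_cell[trace$pre_index] / trace$whole_cell) *
    (trace$roi / trace$roi[trace$pre_index])
  new_normalized_trace(trace, v, "frap_double")
}

#' Full normalization of a FRAP trace
#'
#' Rescales the double-normalized curve between its pre-bleach and bleach
#' values so that the pre-bleach frame equals 1 and the bleach frame equals
#' 0: \code{(v(t) - v(bleach)) / (v(pre) - v(bleach))}. Accepts either a raw
#' \code{\link{intensity_trace}} (double normalization is applied first) or
#' the output of \code{\link{frap_double_normalize}}.
#'
#' @param x an \code{intensity_trace} or a \code{normalized_trace} of kind
#'   \code{"frap_double"}.
#' @return A \code{normalized_trace} of kind \code{"frap_full"}.
#' @export
frap_full_normalize <- function(x) {
  if (inherits(x, "intensity_trace")) x <- frap_double_normalize(x)
  stopifnot(inherits(x, "normalized_trace"))
  if (!identical(x$kind, "frap_double")) {
    stop("full normalization expects a double-normalized FRAP curve",
         call. = FALSE)
  }
  v_pre <- x$values[x$pre_index]
  v_bleach <- x$values[x$bleach_index]
  if (v_pre == v_bleach) {
    stop("no bleach depth: pre-bleach and bleach values are equal",
         call. = FALSE)
  }
  x$values <- (x$values - v_bleach) / (v_pre - v_bleach)
  x$kind <- "frap_full"
  x
}

#' FLIP normalization
#'
#' Divides the monitored (NVJ) intensity by its value before the first
#' bleach pulse: \code{I_FLIP(t) = I_NVJ(t) / I_NVJ,pre-bleach}. The
#' whole-cell channel is ignored.
#'
#' @param trace an \code{\link{intensity_trace}}.
#' @return A \code{normalized_trace} of kind \code{"flip"}.
#' @export
flip_normalize <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (trace$roi[trace$pre_index] <= 0) {
    stop(sprintf("ROI intensity at the pre-bleach frame (%d) is not > 0",
                 trace$pre_index), call. = FALSE)
  }
  new_normalized_trace(trace, trace$roi / trace$roi[trace$pre_index], "flip")
}

#' One-phase exponential fit of a bleaching curve
#'
#' Fits either a one-phase exponential association
#' \eqn{y(t') = Y_\infty (1 - e^{-k t'})} (FRAP recovery after full
#' normalization) or a one-phase exponential decay
#' \eqn{y(t') = y_0 e^{-k t'} + c} (FLIP loss; the offset \eqn{c} is fixed at
#' 0 unless \code{free_offset}), where \eqn{t'} is time measured from the
#' bleach frame. The halftime is \eqn{\ln 2 / k}.
#'
#' Initialization is deterministic: the rate is seeded by a log-linear
#' regression of the transformed curve, the amplitude/plateau by the curve
#' endpoints; there are no random restarts, so identical data give identical
#' fits. The rate is constrained to \eqn{[10^{-6}, 10^{3}]} per second; a
#' fit that fails or pins the rate at a bound is reported with
#' \code{converged = FALSE}, never silently.
#'
#' @param times times in seconds, strictly increasing, already relative to
#'   the bleach frame (\code{t' = 0} at the bleach).
#' @param values normalized intensities.
#' @param kind \code{"association"} or \code{"decay"}.
#' @param free_offset for decay fits, estimate the plateau offset instead of
#'   fixing it at 0?
#' @return An object of class \code{exp_fit}: \code{kind}, \code{rate_k}
#'   (1/s), \code{amplitude}, \code{offset}, \code{halftime} (s),
#'   \code{rmse}, \code{converged}, \code{n}.
#' @export
fit_one_phase <- function(times, values, kind = c("association", "decay"),
                          free_offset = FALSE) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 5 || length(values) != length(times)) {
    stop("need >= 5 points with matching times/values", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  k_lo <- 1e-6
  k_hi <- 1e3
  eps <- 1e-9
  failed <- function() {
    structure(list(kind = kind, rate_k = NA_real_, amplitude = NA_real_,
                   offset = NA_real_, halftime = NA_real_, rmse = NA_real_,
                   converged = FALSE, n = length(times)),
              class = "exp_fit")
  }
  t0 <- times - times[1]
  if (kind == "association") {
    yinf0 <- mean(utils::tail(values, max(3L, length(values) %/% 5L)))
    if (!is.finite(yinf0) || yinf0 <= 0) yinf0 <- max(values, eps)
    z <- pmin(pmax(1 - values / yinf0, eps), 1)
    k0 <- -unname(stats::coef(stats::lm(log(z) ~ t0))[2])
    k0 <- min(max(k0, k_lo * 10), k_hi / 10)
    fit <- tryCatch(
      minpack.lm::nlsLM(values ~ yinf * (1 - exp(-k * t0)),
                        start = list(yinf = yinf0, k = k0),
                        lower = c(yinf = 0, k = k_lo),
                        upper = c(yinf = Inf, k = k_hi),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(failed())
    co <- stats::coef(fit)
    amplitude <- unname(co["yinf"])
    offset <- 0
  } else {
    y0_0 <- max(values[1], eps)
    z <- pmax(values, eps)
    k0 <- -unname(stats::coef(stats::lm(log(z) ~ t0))[2])
    k0 <- min(max(k0, k_lo * 10), k_hi / 10)
    form <- if (free_offset) values ~ y0 * exp(-k * t0) + c0 else
      values ~ y0 * exp(-k * t0)
    start <- if (free_offset) list(y0 = y0_0, k = k0, c0 = 0) else
      list(y0 = y0_0, k = k0)
    lower <- if (free_offset) c(y0 = 0, k = k_lo, c0 = 0) else
      c(y0 = 0, k = k_lo)
    upper <- if (free_offset) c(y0 = Inf, k = k_hi, c0 = Inf) else
      c(y0 = Inf, k = k_hi)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(failed())
    co <- stats::coef(fit)
    amplitude <- unname(co["y0"])
    offset <- if (free_offset) unname(co["c0"]) else 0
  }
  k <- unname(co["k"])
  # a rate pinned at a box bound is not a trustworthy optimum
  at_bound <- k <= k_lo * (1 + 1e-6) || k >= k_hi * (1 - 1e-6)
  resid <- values - stats::predict(fit)
  structure(list(kind = kind, rate_k = k, amplitude = amplitude,
                 offset = offset, halftime = log(2) / k,
                 rmse = sqrt(mean(resid^2)),
                 converged = isTRUE(fit$convInfo$isConv) && !at_bound,
                 n = length(times)),
            class = "exp_fit")
}

#' Fit a normalized photobleaching curve from the bleach frame onward
#'
#' Subsets a normalized trace to its post-bleach frames (the bleach frame
#' defines \code{t' = 0}) and fits the one-phase model appropriate to its
#' kind: association for fully normalized FRAP, decay for FLIP.
#'
#' @param ntrace a \code{normalized_trace}.
#' @param ... passed to \code{\link{fit_one_phase}}.
#' @return An \code{exp_fit}.
#' @export
fit_normalized <- function(ntrace, ...) {
  stopifnot(inherits(ntrace, "normalized_trace"))
  kind <- switch(ntrace$kind,
                 frap_full = "association",
                 flip = "decay",
                 stop("fit a fully normalized FRAP curve or a FLIP curve; ",
                      "got kind '", ntrace$kind, "'", call. = FALSE))
  idx <- ntrace$bleach_index:length(ntrace$times)
  fit_one_phase(ntrace$times[idx] - ntrace$times[ntrace$bleach_index],
                ntrace$values[idx], kind = kind, ...)
}

#' Summarize fitted halftimes per experimental group
#'
#' Non-converged fits are excluded from the statistics and counted.
#'
#' @param fits list of \code{exp_fit} objects.
#' @param groups group label per fit (recycled if length 1).
#' @return Data frame: group, n, excluded, mean_halftime, median_halftime,
#'   sd_halftime.
#' @export
halftime_summary <- function(fits, groups = "all") {
  if (!is.list(fits) || length(fits) == 0L ||
      !all(vapply(fits, inherits, logical(1), "exp_fit"))) {
    stop("'fits' must be a non-empty list of exp_fit objects", call. = FALSE)
  }
  groups <- rep_len(as.character(groups), length(fits))
  ht <- vapply(fits, function(f) f$halftime, numeric(1))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  out <- lapply(unique(groups), function(g) {
    sel <- groups == g
    use <- sel & ok
    if (!any(use)) {
      stop(sprintf("group '%s' has no converged fits", g), call. = FALSE)
    }
    data.frame(group = g, n = sum(use), excluded = sum(sel & !ok),
               mean_halftime = mean(ht[use]),
               median_halftime = stats::median(ht[use]),
               sd_halftime = if (sum(use) > 1) stats::sd(ht[use]) else NA_real_)
  })
  do.call(rbind, out)
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "exp_fit (%s): k = %.4g /s, halftime = %.4g s, rmse = %.3g, %s\n",
    x$kind, x$rate_k, x$halftime, x$rmse,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}
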