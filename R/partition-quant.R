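#' Configuration of the NVJ partitioning quantification
#'
#' Mirrors the Fiji-based workflow the index comes from: background
#' subtraction by a 5-px Gaussian blur, five-pixel-wide line scans across the
#' nuclear envelope, and a strict 2.0 classification threshold on the ratio
#' of line-scan areas.
#'
#' @param blur_sigma Gaussian blur sigma of the background estimate, pixels
#'   (> 0). The Fiji "sigma (radius)" parameter is read as a Gaussian sigma;
#'   users who prefer the radius reading can set their own value here.
#' @param scan_width width of the line scan, pixels (odd positive integer);
#'   intensities are averaged across this width perpendicular to the line.
#' @param scan_length default scan-line length, micrometres.
#' @param partition_threshold ratio above which (strictly) a cell is classed
#'   as NVJ-partitioned.
#' @param clamp_negative clamp negative values after background subtraction
#'   to zero (the behaviour of unsigned-integer image arithmetic)?
#' @return An object of class \code{quant_config}.
#' @export
quant_config <- function(blur_sigma = 5.0, scan_width = 5L, scan_length = 1.5,
                         partition_threshold = 2.0, clamp_negative = TRUE) {
  check_number(blur_sigma, "blur_sigma", lower = 0, strict_lower = TRUE)
  check_number(scan_width, "scan_width", lower = 1)
  if (scan_width != as.integer(scan_width) || as.integer(scan_width) %% 2L == 0L) {
    stop("'scan_width' must be an odd positive integer", call. = FALSE)
  }
  check_number(scan_length, "scan_length", lower = 0, strict_lower = TRUE)
  check_number(partition_threshold, "partition_threshold",
               lower = 0, strict_lower = TRUE)
  structure(list(blur_sigma = blur_sigma,
                 scan_width = as.integer(scan_width),
                 scan_length = scan_length,
                 partition_threshold = partition_threshold,
                 clamp_negative = check_flag(clamp_negative,
                                             "clamp_negative")),
            class = "quant_config")
}

#' Gaussian-blur background subtraction
#'
#' Subtracts a Gaussian-blurred duplicate of the image from the image itself,
#' flattening smooth background and cell-body haze while retaining the sharp
#' NE ring. Negative differences are clamped to zero by default.
#'
#' @param image numeric matrix (single channel).
#' @param cfg a \code{\link{quant_config}}.
#' @return Matrix of the same shape; the \code{pixel_size} attribute, if
#'   present, is preserved.
#' @export
background_subtract <- function(image, cfg = quant_config()) {
  stopifnot(inherits(cfg, "quant_config"))
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a numeric 2-D matrix", call. = FALSE)
  }
  if (anyNA(image)) stop("'image' contains NA/NaN pixels", call. = FALSE)
  bg <- EBImage::gblur(image, sigma = cfg$blur_sigma, boundary = "replicate")
  out <- image - bg
  if (cfg$clamp_negative) out <- pmax(out, 0)
  out <- matrix(out, nrow(image), ncol(image))
  attr(out, "pixel_size") <- attr(image, "pixel_size")
  out
}

# bilinear interpolation at continuous 0-based pixel coordinates
# (row, col); coordinates are clamped to the image border (replicate)
bilinear <- function(image, row, col) {
  nr <- nrow(image)
  nc <- ncol(image)
  row <- pmin(pmax(row, 0), nr - 1)
  col <- pmin(pmax(col, 0), nc - 1)
  r0 <- pmin(floor(row), nr - 2)
  c0 <- pmin(floor(col), nc - 2)
  r0 <- pmax(r0, 0)
  c0 <- pmax(c0, 0)
  fr <- row - r0
  fc <- col - c0
  i00 <- image[cbind(r0 + 1, c0 + 1)]
  i01 <- image[cbind(r0 + 1, c0 + 2)]
  i10 <- image[cbind(r0 + 2, c0 + 1)]
  i11 <- image[cbind(r0 + 2, c0 + 2)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

#' Width-averaged intensity profile along a line
#'
#' Samples the image at one-pixel steps along the segment from the first to
#' the second endpoint. At each step the intensity is the mean of
#' \code{scan_width} bilinear samples spaced one pixel apart perpendicular to
#' the line. The area under the curve (AUC) is the profile sum times the
#' sample spacing in micrometres.
#'
#' @param image numeric matrix; physical scale is taken from its
#'   \code{pixel_size} attribute unless \code{pixel_size} is given.
#' @param line 2x2 matrix: rows are the two endpoints, columns x and y in
#'   micrometres.
#' @param cfg a \code{\link{quant_config}} (supplies \code{scan_width}).
#' @param pixel_size micrometres per pixel.
#' @return An object of class \code{line_scan}: \code{positions} (um along
#'   the line), \code{profile} (width-averaged intensities) and \code{auc}.
#' @export
line_profile <- function(image, line, cfg = quant_config(),
                         pixel_size = attr(image, "pixel_size")) {
  stopifnot(inherits(cfg, "quant_config"))
  if (is.null(pixel_size)) {
    stop("'pixel_size' must be supplied (or attached to the image)",
         call. = FALSE)
  }
  if (!is.matrix(line) || !identical(dim(line), c(2L, 2L))) {
    stop("'line' must be a 2x2 matrix of endpoints (rows) by x/y (columns)",
         call. = FALSE)
  }
  ps <- check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  # endpoint pixel coordinates (0-based, x = col * pixel_size)
  p0 <- line[1, ] / ps
  p1 <- line[2, ] / ps
  nr <- nrow(image)
  nc <- ncol(image)
  for (k in 1:2) {
    p <- rbind(p0, p1)[k, ]
    if (p[1] < 0 || p[1] > nc - 1 || p[2] < 0 || p[2] > nr - 1) {
      stop(sprintf("line endpoint %d at (%.3g, %.3g) um is outside the image",
                   k, line[k, 1], line[k, 2]), call. = FALSE)
    }
  }
  d <- p1 - p0
  len_px <- sqrt(sum(d^2))
  if (len_px == 0) stop("zero-length scan line", call. = FALSE)
  u <- d / len_px                      # unit vector along the line (x, y)
  v <- c(-u[2], u[1])                  # unit normal
  steps <- seq(0, len_px, by = 1)      # one-pixel sampling
  offs <- seq_len(cfg$scan_width) - (cfg$scan_width + 1) / 2
  prof <- vapply(steps, function(s) {
    cx <- p0[1] + s * u[1] + offs * v[1]
    cy <- p0[2] + s * u[2] + offs * v[2]
    mean(bilinear(image, row = cy, col = cx))
  }, numeric(1))
  spacing <- ps                        # one pixel in micrometres
  structure(list(positions = steps * spacing, profile = prof,
                 auc = sum(prof) * spacing),
            class = "line_scan")
}

#' NVJ partitioning index of one cell
#'
#' The index is the ratio of the background-subtracted line-scan area at the
#' NVJ-side NE crossing to the area at the antipodal crossing. A cell is
#' classed as NVJ-partitioned when the ratio strictly exceeds the threshold
#' (a tie at the threshold is not partitioned).
#'
#' @param scan_nvj,scan_opposite \code{line_scan} objects from
#'   \code{\link{line_profile}}.
#' @param cfg a \code{\link{quant_config}} (supplies the threshold).
#' @return An object of class \code{partition_score}: \code{ratio},
#'   \code{partitioned}, and the two AUCs.
#' @export
partition_ratio <- function(scan_nvj, scan_opposite, cfg = quant_config()) {
  stopifnot(inherits(scan_nvj, "line_scan"),
            inherits(scan_opposite, "line_scan"),
            inherits(cfg, "quant_config"))
  a_nvj <- scan_nvj$auc
  a_opp <- scan_opposite$auc
  if (!is.finite(a_nvj) || !is.finite(a_opp)) {
    stop("line-scan AUCs must be finite", call. = FALSE)
  }
  if (a_opp <= 0) {
    stop("opposite-side AUC is <= 0: degenerate background subtraction ",
         "(no NE signal left on the reference side)", call. = FALSE)
  }
  ratio <- a_nvj / a_opp
  structure(list(ratio = ratio,
                 partitioned = ratio > cfg$partition_threshold,
                 auc_nvj = a_nvj, auc_opposite = a_opp),
            class = "partition_score")
}

#' Summarize partitioning over a field of view
#'
#' @param scores non-empty list of \code{partition_score} objects.
#' @return A list: \code{n}, \code{n_partitioned} and
#'   \code{percent_partitioned} (0-100).
#' @export
summarize_field <- function(scores) {
  if (!is.list(scores) || length(scores) == 0L ||
      !all(vapply(scores, inherits, logical(1), "partition_score"))) {
    stop("'scores' must be a non-empty list of partition_score objects",
         call. = FALSE)
  }
  n <- length(scores)
  k <- sum(vapply(scores, function(s) isTRUE(s$partitioned), logical(1)))
  list(n = n, n_partitioned = k, percent_partitioned = 100 * k / n)
}

#' Quantify every cell of a synthetic image from its pixels
#'
#' Runs the full measurement pipeline blind to the ground-truth enrichment:
#' background subtraction of the ring channel, line profiles along the stored
#' NVJ-side and antipodal scan lines, and the partitioning ratio per cell.
#'
#' @param img a \code{synthetic_image} (or a numeric matrix with a
#'   \code{pixel_size} attribute, in which case \code{lines} must be a
#'   data frame in the \code{\link{truth_table}} column layout).
#' @param cfg a \code{\link{quant_config}}.
#' @param lines optional scan-line table overriding the image's own truth.
#' @return Data frame: cell_id, auc_nvj, auc_opposite, ratio, partitioned.
#' @export
quantify_field <- function(img, cfg = quant_config(), lines = NULL) {
  if (inherits(img, "synthetic_image")) {
    image <- img$ring
    if (is.null(lines)) lines <- truth_table(img)
  } else {
    image <- img
    if (is.null(lines)) {
      stop("'lines' is required when 'img' is a plain matrix", call. = FALSE)
    }
  }
  sub <- background_subtract(image, cfg)
  rows <- lapply(seq_len(nrow(lines)), function(i) {
    ln <- lines[i, ]
    sn <- line_profile(sub, rbind(c(ln$nvj_x0, ln$nvj_y0),
                                  c(ln$nvj_x1, ln$nvj_y1)), cfg)
    so <- line_profile(sub, rbind(c(ln$opp_x0, ln$opp_y0),
                                  c(ln$opp_x1, ln$opp_y1)), cfg)
    sc <- partition_ratio(sn, so, cfg)
    data.frame(cell_id = ln$cell_id, auc_nvj = sc$auc_nvj,
               auc_opposite = sc$auc_opposite, ratio = sc$ratio,
               partitioned = sc$partitioned)
  })
  do.call(rbind, rows)
}

#' @export
print.partition_score <- function(x, ...) {
  cat(sprintf("partition_score: ratio = %.4g (%s)\n", x$ratio,
              if (x$partitioned) "NVJ-partitioned" else "not partitioned"))
  invisible(x)
}
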