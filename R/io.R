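#' Write a multi-channel image as a 16-bit multi-page TIFF
#'
#' One page per channel; pixel values must already lie in
#' \code{[0, 65535]} and are stored losslessly.
#'
#' @param img a \code{synthetic_image} or a list of numeric matrices.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  channels <- if (inherits(img, "synthetic_image")) {
    list(ring = img$ring, vacuole = img$vacuole)
  } else if (is.matrix(img)) {
    list(img)
  } else {
    img
  }
  if (!is.list(channels) ||
      !all(vapply(channels, is.matrix, logical(1)))) {
    stop("'img' must be a synthetic_image, a matrix, or a list of matrices",
         call. = FALSE)
  }
  maxv <- 2^16 - 1
  pages <- lapply(channels, function(ch) {
    if (any(ch < 0) || any(ch > maxv)) {
      stop("pixel values must lie in [0, 65535] for 16-bit output",
           call. = FALSE)
    }
    matrix(ch, nrow(ch), ncol(ch)) / maxv
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a (multi-page) TIFF as integer channel matrices
#'
#' Pixel values are returned exactly as stored (no rescaling). Grayscale
#' pages become matrices; an RGB page is an error unless
#' \code{rgb_to_gray = TRUE}, in which case it is converted to a single
#' luminance channel (0.299 R + 0.587 G + 0.114 B, rounded).
#'
#' @param path TIFF file path.
#' @param rgb_to_gray opt in to RGB-to-luminance conversion.
#' @return A list of numeric matrices, one per page.
#' @export
read_image_tiff <- function(path, rgb_to_gray = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (!isTRUE(rgb_to_gray)) {
        stop("multi-sample (RGB) TIFF page: pass rgb_to_gray = TRUE to ",
             "convert to 16-bit luminance", call. = FALSE)
      }
      round(0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3])
    } else {
      matrix(as.numeric(p), nrow(p), ncol(p))
    }
  })
}

#' Write the ground truth of a synthetic image as sidecar JSON
#'
#' @param img a \code{synthetic_image}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(img, path) {
  stopifnot(inherits(img, "synthetic_image"))
  cells <- lapply(img$truth, function(tr) {
    list(center = tr$nucleus_center, radius = tr$nucleus_radius,
         enrichment = tr$enrichment,
         scanline_nvj = unname(apply(tr$scanline_nvj, 1, as.numeric,
                                     simplify = FALSE)),
         scanline_opposite = unname(apply(tr$scanline_opposite, 1,
                                          as.numeric, simplify = FALSE)))
  })
  jsonlite::write_json(list(pixel_size = img$pixel_size, cells = cells),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read scan-line annotations (sidecar JSON or CSV)
#'
#' Accepts the JSON written by \code{\link{write_ground_truth}} or a CSV
#' with columns \code{cell_id, x0, y0, x1, y1, side} where \code{side} is
#' \code{"nvj"} or \code{"opposite"}.
#'
#' @param path annotation file (.json or .csv).
#' @return Data frame in the \code{\link{truth_table}} scan-line layout,
#'   with a \code{pixel_size} attribute when the JSON provides one.
#' @export
read_scan_lines <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    gt <- jsonlite::read_json(path, simplifyVector = TRUE)
    cells <- gt$cells
    n <- if (is.data.frame(cells)) nrow(cells) else length(cells)
    to_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
    rows <- lapply(seq_len(n), function(i) {
      ci <- if (is.data.frame(cells)) lapply(cells, `[[`, i) else cells[[i]]
      sn <- to_mat(ci$scanline_nvj)
      so <- to_mat(ci$scanline_opposite)
      data.frame(cell_id = i,
                 nvj_x0 = sn[1, 1], nvj_y0 = sn[1, 2],
                 nvj_x1 = sn[2, 1], nvj_y1 = sn[2, 2],
                 opp_x0 = so[1, 1], opp_y0 = so[1, 2],
                 opp_x1 = so[2, 1], opp_y1 = so[2, 2])
    })
    out <- do.call(rbind, rows)
    attr(out, "pixel_size") <- gt$pixel_size
    out
  } else {
    d <- utils::read.csv(path)
    need <- c("cell_id", "x0", "y0", "x1", "y1", "side")
    if (!all(need %in% names(d))) {
      stop("scan-line CSV needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    ids <- unique(d$cell_id)
    rows <- lapply(ids, function(id) {
      sn <- d[d$cell_id == id & d$side == "nvj", ][1, ]
      so <- d[d$cell_id == id & d$side == "opposite", ][1, ]
      if (anyNA(sn$x0) || anyNA(so$x0)) {
        stop(sprintf("cell %s needs one 'nvj' and one 'opposite' line", id),
             call. = FALSE)
      }
      data.frame(cell_id = id,
                 nvj_x0 = sn$x0, nvj_y0 = sn$y0,
                 nvj_x1 = sn$x1, nvj_y1 = sn$y1,
                 opp_x0 = so$x0, opp_y0 = so$y0,
                 opp_x1 = so$x1, opp_y1 = so$y1)
    })
    do.call(rbind, rows)
  }
}

#' Write an intensity trace in the trace-CSV dialect
#'
#' Columns \code{time_s, roi, whole_cell} preceded by comment headers
#' \code{# pre_index=<int>} and \code{# bleach_index=<int>}.
#'
#' @param trace an \code{\link{intensity_trace}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pre_index=%d", trace$pre_index),
               sprintf("# bleach_index=%d", trace$bleach_index)), con)
  d <- data.frame(time_s = trace$times, roi = trace$roi)
  if (!is.null(trace$whole_cell)) d$whole_cell <- trace$whole_cell
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' Read an intensity trace from the trace-CSV dialect
#'
#' @param path trace CSV written by \code{\link{write_trace_csv}} (or by
#'   hand following the same dialect).
#' @return An \code{\link{intensity_trace}}.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  hdr <- readLines(path, n = 10L)
  grab <- function(key) {
    ln <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (length(ln) == 0L) {
      stop(sprintf("trace CSV is missing the '# %s=' header", key),
           call. = FALSE)
    }
    as.integer(sub(sprintf("^#\\s*%s=", key), "", ln[1]))
  }
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "roi") %in% names(d))) {
    stop("trace CSV needs columns time_s and roi", call. = FALSE)
  }
  intensity_trace(times = d$time_s, roi = d$roi,
                  whole_cell = if ("whole_cell" %in% names(d))
                    d$whole_cell else NULL,
                  pre_index = grab("pre_index"),
                  bleach_index = grab("bleach_index"))
}

cli_usage <- function() {
  paste(
    "usage: nvjquant <command> [options]",
    "",
    "commands:",
    "  simulate-image --config cfg.json --seed N --out img.tif",
    "  quantify       --image img.tif --lines lines.json --out scores.csv",
    "                 [--pixel-size um]",
    "  simulate-bleach --protocol frap|flip --out dir/ [--params p.json]",
    "  fit            --traces dir/ --kind frap|flip --out fits.csv",
    "  resume         --records r.csv --groups A,B --out dir/",
    sep = "\n"
  )
}

parse_cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    key <- argv[i]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key,
                                     call. = FALSE)
    if (i == length(argv)) stop("missing value for ", key, call. = FALSE)
    out[[sub("^--", "", key)]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands listed by the usage message onto the package
#' functions; designed to be called from a thin Rscript wrapper (see
#' \code{inst/cli/nvjquant.R}). Validation errors print to stderr and give
#' exit code 1; an unknown or missing subcommand prints the usage and gives
#' exit code 2.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L || !argv[1] %in%
      c("simulate-image", "quantify", "simulate-bleach", "fit", "resume")) {
    message(cli_usage())
    return(invisible(2L))
  }
  cmd <- argv[1]
  code <- tryCatch({
    opts <- parse_cli_args(argv[-1])
    switch(cmd,
      "simulate-image" = cli_simulate_image(opts),
      "quantify" = cli_quantify(opts),
      "simulate-bleach" = cli_simulate_bleach(opts),
      "fit" = cli_fit(opts),
      "resume" = cli_resume(opts)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

cli_need <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss) > 0) {
    stop("missing required option(s): ",
         paste0("--", miss, collapse = ", "), call. = FALSE)
  }
}

cli_simulate_image <- function(opts) {
  cli_need(opts, c("config", "out"))
  cfg <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
  img_args <- as.list(cfg$imaging %||% list())
  if (!is.null(opts$seed)) img_args$rng_seed <- as.integer(opts$seed)
  icfg <- do.call(imaging_config, img_args)
  cells <- cfg$cells
  n <- if (is.data.frame(cells)) nrow(cells) else length(cells)
  specs <- lapply(seq_len(n), function(i) {
    ci <- if (is.data.frame(cells)) as.list(cells[i, ]) else cells[[i]]
    ci <- lapply(ci, unlist)
    # cells may specify different subsets of fields; drop the unspecified
    ci <- ci[!vapply(ci, function(x) is.null(x) || all(is.na(x)), logical(1))]
    do.call(cell_spec, ci)
  })
  img <- render_field(specs, icfg)
  write_image_tiff(img, opts$out)
  write_ground_truth(img, sub("\\.tiff?$", ".json", opts$out))
  message("wrote ", opts$out)
}

cli_quantify <- function(opts) {
  cli_need(opts, c("image", "lines", "out"))
  channels <- read_image_tiff(opts$image)
  lines <- read_scan_lines(opts$lines)
  ps <- if (!is.null(opts[["pixel-size"]])) as.numeric(opts[["pixel-size"]])
        else attr(lines, "pixel_size")
  if (is.null(ps)) {
    stop("pixel size unavailable: pass --pixel-size or use JSON annotations",
         call. = FALSE)
  }
  image <- channels[[1]]
  attr(image, "pixel_size") <- ps
  scores <- quantify_field(image, lines = lines)
  utils::write.csv(scores, opts$out, row.names = FALSE)
  fs <- summarize_field(apply(scores, 1, function(r) {
    structure(list(ratio = as.numeric(r[["ratio"]]),
                   partitioned = as.logical(r[["partitioned"]])),
              class = "partition_score")
  }))
  utils::write.csv(
    data.frame(n = fs$n, n_partitioned = fs$n_partitioned,
               percent_partitioned = fs$percent_partitioned),
    sub("\\.csv$", "_field.csv", opts$out), row.names = FALSE)
  message("wrote ", opts$out)
}

cli_simulate_bleach <- function(opts) {
  cli_need(opts, c("protocol", "out"))
  params <- if (!is.null(opts$params)) {
    do.call(ring_params, jsonlite::read_json(opts$params,
                                             simplifyVector = TRUE))
  } else {
    demo_ring_params(retained = TRUE)
  }
  proto <- switch(opts$protocol,
                  frap = protocol_frap(params$circumference),
                  flip = protocol_flip(params$circumference),
                  stop("--protocol must be 'frap' or 'flip'", call. = FALSE))
  sim <- simulate_photobleach(params, proto,
                              seed = as.integer(opts$seed %||% 1L))
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$traces)) {
    write_trace_csv(sim$traces[[nm]],
                    file.path(opts$out, paste0(nm, ".csv")))
  }
  jsonlite::write_json(
    list(params = unclass(params), protocol_kind = proto$kind,
         roi_area_label = proto$roi_area_label),
    file.path(opts$out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  message("wrote traces to ", opts$out)
}

cli_fit <- function(opts) {
  cli_need(opts, c("traces", "kind", "out"))
  files <- list.files(opts$traces, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no trace CSVs found in ", opts$traces, call. = FALSE)
  }
  rows <- lapply(files, function(f) {
    tr <- read_trace_csv(f)
    ntr <- switch(opts$kind,
                  frap = frap_full_normalize(tr),
                  flip = flip_normalize(tr),
                  stop("--kind must be 'frap' or 'flip'", call. = FALSE))
    fit <- fit_normalized(ntr)
    data.frame(trace_id = sub("\\.csv$", "", basename(f)), kind = fit$kind,
               k_per_s = fit$rate_k, halftime_s = fit$halftime,
               rmse = fit$rmse, converged = fit$converged)
  })
  utils::write.csv(do.call(rbind, rows), opts$out, row.names = FALSE)
  message("wrote ", opts$out)
}

cli_resume <- function(opts) {
  cli_need(opts, c("records", "groups", "out"))
  records <- utils::read.csv(opts$records)
  groups <- strsplit(opts$groups, ",")[[1]]
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  curves <- resumption_curve(records)
  utils::write.csv(curves, file.path(opts$out, "curves.csv"),
                   row.names = FALSE)
  if (length(groups) == 2L) {
    ks <- compare_resumption(records, groups)
    jsonlite::write_json(ks, file.path(opts$out, "ks.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  message("wrote resumption outputs to ", opts$out)
}
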