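stack_channels <- c("marker", "draq7", "bodipy_green", "bodipy_red")

#' Render a synthetic multi-channel time-lapse stack
#'
#' Each cell is drawn as an isotropic Gaussian blob centred on its centroid
#' with per-channel width
#' `sigma = sqrt((blob_frac * diameter)^2 + (psf_sigma * pixel_size)^2)`
#' (stain extent convolved with the point-spread function): the transfection
#' marker and the membrane probe fill the cell, the nuclear death dye only
#' its nucleus. Channel dynamics follow the event table:
#'
#' * `marker`: constant peak amplitude `gains["marker"]` for transfected
#'   cells, dark for bystanders;
#' * `draq7`: steps from 0 to `gains["draq7"]` at frames with
#'   `time >= draq7_time`;
#' * `bodipy_green`/`bodipy_red`: peak amplitudes `gain * f(t)` and
#'   `gain * (1 - f(t))` with oxidized fraction
#'   `f(t) = b + (1 - b)(1 - exp(-(t - onset)/tau))` after oxidation onset
#'   and `b = bodipy_baseline` before, so green + red is conserved per cell
#'   (up to noise) when the two gains are equal.
#'
#' Per-channel offsets and additive Gaussian read noise are applied last. A
#' ground-truth label map (discs at the configured radii, overlaps resolved
#' to the nearest centroid) is attached for end-to-end validation of the
#' quantification pipeline.
#'
#' @param cells a `cell_table`.
#' @param events the matching `event_table`.
#' @param imaging an [imaging_config()].
#' @param t_end last frame time, minutes (defaults to the event table's
#'   assay window).
#' @return a `frame_stack`: list with `frames` (array
#'   `[row, col, channel, frame]`), `frame_times`, `channels`, `pixel_size`,
#'   `frame_interval`, `field_size` and `label_map` (a `label_map` object,
#'   see [segment_cells()]).
#' @export
render_frames <- function(cells, events, imaging,
                          t_end = attr(events, "t_end")) {
  if (!inherits(imaging, "imaging_config"))
    stopf("`imaging` must be built with imaging_config()")
  if (is.null(t_end)) stopf("`t_end` is required")
  if (imaging$frame_interval > t_end)
    stopf("`frame_interval` exceeds the assay window")
  L <- attr(cells, "field_size") %||% max(cells$x + cells$diameter / 2,
                                          cells$y + cells$diameter / 2, 0)
  px <- imaging$pixel_size
  npx <- as.integer(ceiling(L / px))
  if (npx < 2L) stopf("pixel field too small")
  n <- nrow(cells)
  if (n && (max(cells$x, cells$y) > npx * px || min(cells$x, cells$y) < 0))
    stopf("pixel field too small to contain all cells")
  times <- seq(0, t_end, by = imaging$frame_interval)
  nt <- length(times)
  arr <- array(0, dim = c(npx, npx, 4L, nt),
               dimnames = list(NULL, NULL, stack_channels, NULL))

  ev <- events[match(cells$id, events$id), , drop = FALSE]
  # per-cell, per-channel blob widths (stain extent (+) psf, in um)
  sigma <- vapply(stack_channels, function(ch)
    sqrt((imaging$blob_frac[[ch]] * cells$diameter)^2 +
           (imaging$psf_sigma * px)^2), numeric(n))
  if (n == 1L) sigma <- matrix(sigma, nrow = 1L,
                               dimnames = list(NULL, stack_channels))

  # per-cell, per-channel pixel patch (rows, cols, unit-peak Gaussian kernel)
  patches <- vector("list", n)
  for (i in seq_len(n)) {
    s_max <- max(sigma[i, ])
    half <- ceiling(4 * s_max / px)
    r0 <- floor(cells$y[i] / px) + 1L
    c0 <- floor(cells$x[i] / px) + 1L
    rows <- max(1L, r0 - half):min(npx, r0 + half)
    cols <- max(1L, c0 - half):min(npx, c0 + half)
    yc <- (rows - 0.5) * px
    xc <- (cols - 0.5) * px
    d2 <- outer((yc - cells$y[i])^2, (xc - cells$x[i])^2, "+")
    kerns <- lapply(stack_channels, function(ch)
      exp(-d2 / (2 * sigma[i, ch]^2)))
    names(kerns) <- stack_channels
    patches[[i]] <- list(rows = rows, cols = cols, kerns = kerns)
  }

  b <- imaging$bodipy_baseline
  ox_frac <- function(t, onset) {
    f <- rep(b, length(onset))
    on <- !is.na(onset) & t >= onset
    f[on] <- b + (1 - b) * (1 - exp(-(t - onset[on]) / imaging$bodipy_tau))
    f
  }
  transf <- cells$population == "transfected"
  for (k in seq_len(nt)) {
    t <- times[k]
    f <- ox_frac(t, ev$ox_onset_time)
    draq_on <- !is.na(ev$draq7_time) & t >= ev$draq7_time
    amp <- cbind(marker = ifelse(transf, imaging$gains[["marker"]], 0),
                 draq7 = ifelse(draq_on, imaging$gains[["draq7"]], 0),
                 bodipy_green = imaging$gains[["bodipy_green"]] * f,
                 bodipy_red = imaging$gains[["bodipy_red"]] * (1 - f))
    for (i in seq_len(n)) {
      p <- patches[[i]]
      for (ch in 1:4) {
        a <- amp[i, ch]
        if (a > 0)
          arr[p$rows, p$cols, ch, k] <- arr[p$rows, p$cols, ch, k] +
            a * p$kerns[[ch]]
      }
    }
  }
  for (ch in 1:4)
    arr[, , ch, ] <- arr[, , ch, ] + imaging$offsets[[stack_channels[ch]]]
  if (imaging$noise_sd > 0) {
    withr::with_seed(imaging$seed, {
      arr <- arr + rnorm(length(arr), 0, imaging$noise_sd)
    })
  }

  # ground-truth label map: discs, overlap resolved to the nearest centroid
  labels <- matrix(0L, npx, npx)
  bestd <- matrix(Inf, npx, npx)
  for (i in seq_len(n)) {
    r <- cells$diameter[i] / 2
    half <- ceiling(r / px) + 1L
    r0 <- floor(cells$y[i] / px) + 1L
    c0 <- floor(cells$x[i] / px) + 1L
    rows <- max(1L, r0 - half):min(npx, r0 + half)
    cols <- max(1L, c0 - half):min(npx, c0 + half)
    yc <- (rows - 0.5) * px
    xc <- (cols - 0.5) * px
    d2 <- outer((yc - cells$y[i])^2, (xc - cells$x[i])^2, "+")
    inside <- d2 <= r^2 & d2 < bestd[rows, cols]
    sub <- labels[rows, cols]
    sub[inside] <- cells$id[i]
    labels[rows, cols] <- sub
    bd <- bestd[rows, cols]
    bd[inside] <- d2[inside]
    bestd[rows, cols] <- bd
  }
  areas <- tabulate(labels[labels > 0L], nbins = max(cells$id, 1L))
  lm_table <- data.frame(label = cells$id, x = cells$x, y = cells$y,
                         area_um2 = areas[cells$id] * px^2)
  label_map <- structure(list(labels = labels, table = lm_table,
                              pixel_size = px), class = "label_map")

  structure(list(frames = arr, frame_times = times, channels = stack_channels,
                 pixel_size = px, frame_interval = imaging$frame_interval,
                 field_size = L, label_map = label_map,
                 imaging = imaging),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames x %d channels, %d x %d px (%g um/px)\n",
              length(x$frame_times), length(x$channels),
              dim(x$frames)[1L], dim(x$frames)[2L], x$pixel_size))
  invisible(x)
}

#' Extract one image plane from a frame stack
#'
#' @param stack a `frame_stack`.
#' @param frame frame index (1-based).
#' @param channel channel name or index.
#' @return numeric matrix `[row, col]`.
#' @export
get_frame <- function(stack, frame = 1L, channel = "marker") {
  if (is.character(channel)) channel <- match(channel, stack$channels)
  stack$frames[, , channel, frame]
}

#' Write or read a frame stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered frame-major, channel-minor (`(T, C)` order). Intensities
#' are stored as 16-bit integers with a global scale factor recorded in the
#' sidecar together with pixel size, frame interval, frame times and channel
#' names. The ground-truth label map, when present, is written alongside as
#' `<base>_labels.tif`.
#'
#' @param stack a `frame_stack`.
#' @param path TIFF output path; the sidecar is `<path>.json`.
#' @return `read_frame_stack()` returns a `frame_stack` (without label map
#'   unless one was written); `write_frame_stack()` returns `path` invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  arr <- stack$frames
  lo <- min(arr)
  scale <- max(arr) - lo
  if (scale <= 0) scale <- 1
  nt <- length(stack$frame_times)
  nc <- length(stack$channels)
  pages <- vector("list", nt * nc)
  for (k in seq_len(nt)) for (ch in seq_len(nc))
    pages[[(k - 1L) * nc + ch]] <- (arr[, , ch, k] - lo) / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pixel_size = stack$pixel_size,
               frame_interval = stack$frame_interval,
               frame_times = stack$frame_times,
               channels = stack$channels,
               field_size = stack$field_size,
               intensity_offset = lo, intensity_scale = scale,
               n_frames = nt, n_channels = nc)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(stack$label_map)) {
    lab <- stack$label_map$labels
    tiff::writeTIFF(lab / max(1L, max(lab)), sub("\\.tiff?$", "", path) |>
                      paste0("_labels.tif"), bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nt <- meta$n_frames; nc <- meta$n_channels
  npx <- dim(pages[[1L]])
  arr <- array(0, dim = c(npx[1L], npx[2L], nc, nt),
               dimnames = list(NULL, NULL, meta$channels, NULL))
  for (k in seq_len(nt)) for (ch in seq_len(nc))
    arr[, , ch, k] <- pages[[(k - 1L) * nc + ch]] * meta$intensity_scale +
      meta$intensity_offset
  structure(list(frames = arr, frame_times = meta$frame_times,
                 channels = meta$channels, pixel_size = meta$pixel_size,
                 frame_interval = meta$frame_interval,
                 field_size = meta$field_size, label_map = NULL),
            class = "frame_stack")
}
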