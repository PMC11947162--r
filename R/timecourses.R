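#' Extract background-corrected per-cell intensity timecourses
#'
#' For every cell, channel and frame: the mean intensity over the cell's
#' label pixels minus a background estimate, clipped at zero. Using the mean
#' (intensity per pixel) rather than the integrated sum is the cell-size
#' correction. Background modes:
#'
#' * `"local"` (default): median intensity in a 3-pixel dilation annulus
#'   around the cell, excluding all labelled pixels; cells whose annulus is
#'   empty (densely packed fields) fall back to the global estimate with a
#'   warning.
#' * `"global"`: median over all unlabelled pixels of the frame.
#'
#' @param stack a `frame_stack`.
#' @param labels a `label_map`; defaults to the stack's ground-truth map.
#' @param background `"local"` or `"global"`.
#' @param annulus_px annulus width in pixels for local background.
#' @return a `cell_timecourses`: data frame with columns `cell`, `frame`,
#'   `time`, `channel`, `value`; attributes `areas` (data frame `cell`,
#'   `area_um2`), `frame_times`, `channels`.
#' @export
extract_timecourses <- function(stack, labels = NULL,
                                background = c("local", "global"),
                                annulus_px = 3L) {
  background <- match.arg(background)
  labels <- labels %||% stack$label_map
  if (is.null(labels)) stopf("no label map supplied and none on the stack")
  lab <- labels$labels
  if (!all(dim(lab) == dim(stack$frames)[1:2]))
    stopf("label map geometry does not match the stack")
  ids <- labels$table$label
  nl <- length(ids)
  if (!nl) stopf("label map contains no cells")

  cell_idx <- split(which(lab > 0L), lab[lab > 0L])
  cell_idx <- cell_idx[match(as.character(ids), names(cell_idx))]
  bg_global_idx <- which(lab == 0L)

  ann_idx <- vector("list", nl)
  fell_back <- FALSE
  if (background == "local") {
    nr <- nrow(lab); nc <- ncol(lab)
    brush <- EBImage::makeBrush(2L * annulus_px + 1L, shape = "disc")
    for (k in seq_len(nl)) {
      idx <- cell_idx[[k]]
      rows <- (idx - 1L) %% nr + 1L
      cols <- (idx - 1L) %/% nr + 1L
      r1 <- max(1L, min(rows) - annulus_px - 1L)
      r2 <- min(nr, max(rows) + annulus_px + 1L)
      c1 <- max(1L, min(cols) - annulus_px - 1L)
      c2 <- min(nc, max(cols) + annulus_px + 1L)
      crop <- matrix(0, r2 - r1 + 1L, c2 - c1 + 1L)
      crop[cbind(rows - r1 + 1L, cols - c1 + 1L)] <- 1
      dil <- EBImage::dilate(crop, brush) > 0
      ann_local <- dil & lab[r1:r2, c1:c2] == 0L
      w <- which(ann_local)
      ann_idx[[k]] <- (c1 - 1L + (w - 1L) %/% nrow(crop)) * nr +
        (r1 + (w - 1L) %% nrow(crop))
      if (!length(ann_idx[[k]])) fell_back <- TRUE
    }
    if (fell_back)
      warning("empty local-background annulus for >=1 cell; ",
              "falling back to global background for those cells",
              call. = FALSE)
  }

  nt <- length(stack$frame_times)
  nc_ch <- length(stack$channels)
  res <- vector("list", nt * nc_ch)
  pos <- 0L
  for (ch in seq_len(nc_ch)) {
    for (k in seq_len(nt)) {
      m <- stack$frames[, , ch, k]
      gbg <- median(m[bg_global_idx])
      vals <- vapply(seq_len(nl), function(l) {
        v <- mean(m[cell_idx[[l]]])
        bg <- if (background == "local" && length(ann_idx[[l]]))
          median(m[ann_idx[[l]]]) else gbg
        max(0, v - bg)
      }, numeric(1))
      pos <- pos + 1L
      res[[pos]] <- data.frame(cell = ids, frame = k,
                               time = stack$frame_times[k],
                               channel = stack$channels[ch], value = vals,
                               stringsAsFactors = FALSE)
    }
  }
  tc <- do.call(rbind, res)
  attr(tc, "areas") <- data.frame(cell = ids,
                                  area_um2 = labels$table$area_um2)
  attr(tc, "frame_times") <- stack$frame_times
  attr(tc, "channels") <- stack$channels
  class(tc) <- c("cell_timecourses", "data.frame")
  tc
}

# cells x frames matrix for one channel
tc_matrix <- function(tc, channel) {
  sub <- tc[tc$channel == channel, , drop = FALSE]
  if (!nrow(sub)) stopf("channel `%s` not present in the timecourses", channel)
  cells <- sort(unique(sub$cell))
  frames <- sort(unique(sub$frame))
  m <- matrix(NA_real_, length(cells), length(frames),
              dimnames = list(cells, frames))
  m[cbind(match(sub$cell, cells), match(sub$frame, frames))] <- sub$value
  m
}

#' Classify cells as transfected or bystander from a marker channel
#'
#' A cell is transfected when its time-averaged marker intensity over the
#' pre-activation frames reaches `threshold`. With `threshold = "auto"` the
#' split maximizing between-class variance of the per-cell marker
#' distribution is used; a distribution without clear bimodality (separation
#' of the two classes below 4 pooled within-class SDs) raises an error
#' advising an explicit threshold.
#'
#' @param tc a `cell_timecourses`.
#' @param marker_channel channel name.
#' @param threshold numeric intensity, or `"auto"`.
#' @param pre_frames number of initial (pre-activation) frames to average.
#' @return data frame `cell`, `marker_mean`, `population`; attribute
#'   `threshold`.
#' @export
classify_populations <- function(tc, marker_channel = "marker",
                                 threshold = "auto", pre_frames = 1L) {
  m <- tc_matrix(tc, marker_channel)
  v <- rowMeans(m[, seq_len(min(pre_frames, ncol(m))), drop = FALSE])
  if (identical(threshold, "auto")) {
    th <- otsu_split(v)
    if (attr(th, "separation") < 4)
      stopf(paste0("marker distribution appears unimodal (separation %.2f); ",
                   "supply an explicit threshold"), attr(th, "separation"))
    threshold <- as.numeric(th)
  }
  out <- data.frame(cell = as.integer(rownames(m)), marker_mean = unname(v),
                    population = ifelse(v >= threshold, "transfected",
                                        "bystander"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

#' Call per-cell death times from a DRAQ7 channel
#'
#' Death is called at the first frame whose corrected DRAQ7 intensity reaches
#' `threshold` and stays at or above it for `persistence` consecutive frames;
#' cells never satisfying the rule are censored (`NA`) at the last frame.
#' With `threshold = "auto"` the threshold is the pre-activation mean plus
#' five SDs of the DRAQ7 values across cells.
#'
#' @param tc a `cell_timecourses`.
#' @param draq7_channel channel name.
#' @param threshold numeric, or `"auto"`.
#' @param persistence required consecutive frames at/above threshold (>= 1).
#' @param pre_frames frames treated as pre-activation for `"auto"`.
#' @return data frame `cell`, `death_time` (minutes, `NA` = censored),
#'   `censored`; attributes `threshold`, `censor_time`.
#' @export
call_death <- function(tc, draq7_channel = "draq7", threshold = "auto",
                       persistence = 2L, pre_frames = 1L) {
  if (persistence < 1L) stopf("`persistence` must be >= 1")
  m <- tc_matrix(tc, draq7_channel)
  times <- attr(tc, "frame_times") %||% sort(unique(tc$time))
  if (identical(threshold, "auto")) {
    pre <- m[, seq_len(min(pre_frames, ncol(m))), drop = FALSE]
    threshold <- mean(pre) + 5 * sd(as.numeric(pre))
    if (!is.finite(threshold)) threshold <- mean(pre)
  }
  call_one <- function(v) {
    above <- v >= threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= persistence)
    if (!length(ok)) return(NA_real_)
    times[starts[ok[1L]]]
  }
  dt <- apply(m, 1L, call_one)
  out <- data.frame(cell = as.integer(rownames(m)), death_time = unname(dt),
                    censored = is.na(unname(dt)), stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "censor_time") <- times[length(times)]
  out
}

#' Ratiometric lipid-peroxidation oxidation ratio
#'
#' The oxidized fraction of the C11-BODIPY probe, `G / (G + R)` with G the
#' oxidized (green) and R the reduced (red) intensity, bounded in \[0, 1\].
#' Entries with `G + R = 0` are undefined and returned as `NA`, with their
#' positions recorded in the `"undefined"` attribute (never silently zeroed).
#' `formula = "total_over_green"` returns `(G + R) / G` instead, an
#' unbounded variant of the same monotone quantity.
#'
#' @param green,red non-negative scalars or equal-length vectors.
#' @param formula `"green_over_total"` (default) or `"total_over_green"`.
#' @return numeric scalar or vector; attribute `undefined` holds the indices
#'   where the ratio is undefined (if any).
#' @examples
#' oxidation_ratio(100, 0)   # 1
#' oxidation_ratio(50, 50)   # 0.5
#' @export
oxidation_ratio <- function(green, red,
                            formula = c("green_over_total",
                                        "total_over_green")) {
  formula <- match.arg(formula)
  if (length(green) != length(red))
    stopf("`green` and `red` must have equal length")
  if (any(green < 0, na.rm = TRUE) || any(red < 0, na.rm = TRUE))
    stopf("intensities must be non-negative")
  tot <- green + red
  bad <- which(if (formula == "green_over_total") tot == 0 else green == 0)
  r <- if (formula == "green_over_total") green / tot else tot / green
  r[bad] <- NA_real_
  if (length(bad)) attr(r, "undefined") <- bad
  r
}
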