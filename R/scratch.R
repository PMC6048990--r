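#' Rotate an image stack clockwise
#'
#' Scratches must be horizontal before band detection. Multiples of 90
#' degrees are rotated losslessly by index permutation; any other angle is
#' rotated about the frame centre with bilinear interpolation, zero fill,
#' and an output frame enlarged to contain the whole rotated image. All
#' frames are rotated identically.
#'
#' @param stack An [image_stack()].
#' @param degrees_clockwise Finite rotation angle in degrees.
#' @return The rotated [image_stack()].
#' @export
rotate_stack <- function(stack, degrees_clockwise) {
  stopifnot(inherits(stack, "image_stack"), is.finite(degrees_clockwise))
  deg <- degrees_clockwise %% 360
  if (deg == 0) return(stack)
  image_stack(lapply(stack$frames, rotate_frame, degrees_clockwise = deg))
}

rotate90cw <- function(m) t(m[nrow(m):1L, , drop = FALSE])

rotate_frame <- function(m, degrees_clockwise) {
  deg <- degrees_clockwise %% 360
  if (deg %% 90 == 0) {
    k <- (deg %/% 90) %% 4
    for (i in seq_len(k)) m <- rotate90cw(m)
    return(m)
  }
  h <- nrow(m); w <- ncol(m)
  theta <- deg * pi / 180
  ct <- cos(theta); st <- sin(theta)
  h2 <- ceiling(h * abs(ct) + w * abs(st))
  w2 <- ceiling(h * abs(st) + w * abs(ct))
  # inverse map: rotate output coordinates counterclockwise about centres
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  cr2 <- (h2 - 1) / 2; cc2 <- (w2 - 1) / 2
  rr <- matrix(seq_len(h2) - 1 - cr2, h2, w2)
  ccm <- matrix(rep(seq_len(w2) - 1 - cc2, each = h2), h2, w2)
  # clockwise image rotation: source = R(theta) %*% dest in (row, col) axes
  src_r <- ct * rr - st * ccm + cr
  src_c <- st * rr + ct * ccm + cc
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  get_px <- function(ri, ci) {
    ok <- ri >= 0 & ri <= h - 1 & ci >= 0 & ci <= w - 1
    out <- numeric(length(ri))
    out[ok] <- m[cbind(ri[ok] + 1, ci[ok] + 1)]
    out
  }
  v <- (1 - fr) * (1 - fc) * get_px(r0, c0) +
    (1 - fr) * fc * get_px(r0, c0 + 1) +
    fr * (1 - fc) * get_px(r0 + 1, c0) +
    fr * fc * get_px(r0 + 1, c0 + 1)
  matrix(pmax(v, 0), h2, w2)
}

#' Cell-frequency histogram along the image rows
#'
#' Bins partition `[0, height)` into half-open intervals of `bin_height`
#' pixel rows; a nucleus falls in bin `floor(centroid_row / bin_height)`.
#' The scratch is a run of empty bins in this histogram at the first
#' timepoint.
#'
#' @param nuclei Feature data frame (needs a `centroid_row` column).
#' @param height Frame height in pixels.
#' @param bin_height Bin size in pixel rows (>= 1).
#' @return Integer vector of counts, one per bin.
#' @export
y_frequency <- function(nuclei, height, bin_height) {
  stopifnot(bin_height >= 1, height >= 1)
  n_bins <- ceiling(height / bin_height)
  if (is.null(nuclei) || nrow(nuclei) == 0L) return(integer(n_bins))
  bins <- floor(nuclei$centroid_row / bin_height)
  tabulate(bins + 1L, nbins = n_bins)
}

#' Detect the scratch band from a cell-frequency histogram
#'
#' The main gap is the longest run of zero-count bins (ties broken by the
#' run whose centre lies nearest the vertical image centre, since scratches
#' are introduced mid-well). To avoid underestimating the scratch when
#' stray cells remain inside it, neighbouring zero runs separated from the
#' current band by at most `merge_span_bins` bins, each holding at most
#' `straggler_max` cells, are absorbed; the search iterates outwards above
#' and below the band until no merge applies.
#'
#' @param histogram Integer counts per bin from [y_frequency()].
#' @param bin_height Bin size in pixel rows.
#' @param height Frame height in pixels.
#' @param merge_span_bins Maximum length, in bins, of an occupied run that
#'   may be bridged (default 2).
#' @param straggler_max Maximum cells per bridged bin (default 2).
#' @return A `scratch_band` object: `y_low` (inclusive pixel row), `y_high`
#'   (exclusive), `bin_height`, and `merged_gaps`, a list of the pixel-row
#'   intervals of occupied bins absorbed into the band. A band narrower
#'   than is plausible for a scratch raises a warning, not an error.
#' @export
detect_scratch_band <- function(histogram, bin_height, height,
                                merge_span_bins = 2L, straggler_max = 2L) {
  n <- length(histogram)
  stopifnot(n >= 1L, bin_height >= 1)
  if (!any(histogram == 0L)) {
    stop("detection error: no cell-free area found", call. = FALSE)
  }
  r <- rle(histogram == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zero_runs <- which(r$values)
  len <- r$lengths[zero_runs]
  best_len <- max(len)
  cand <- zero_runs[len == best_len]
  if (length(cand) > 1L) {
    centre_px <- height / 2
    mid_px <- ((starts[cand] + ends[cand]) / 2 - 0.5) * bin_height
    cand <- cand[which.min(abs(mid_px - centre_px))]
  }
  lo <- starts[cand[1L]]; hi <- ends[cand[1L]]  # 1-based bin interval

  merged <- list()
  repeat {
    extended <- FALSE
    # upward: the occupied run between the band and the next zero run above
    if (lo > 1L) {
      j <- lo - 1L
      while (j >= 1L && histogram[j] > 0L) j <- j - 1L
      bridge <- seq2(j + 1L, lo - 1L)
      if (j >= 1L && length(bridge) <= merge_span_bins &&
          all(histogram[bridge] <= straggler_max)) {
        merged <- c(merged, list(c((j + 1L - 1L) * bin_height, (lo - 1L) * bin_height)))
        i <- j
        while (i >= 1L && histogram[i] == 0L) i <- i - 1L
        lo <- i + 1L
        extended <- TRUE
      }
    }
    # downward: the occupied run between the band and the next zero run below
    if (hi < n) {
      j <- hi + 1L
      while (j <= n && histogram[j] > 0L) j <- j + 1L
      bridge <- seq2(hi + 1L, j - 1L)
      if (j <= n && length(bridge) <= merge_span_bins &&
          all(histogram[bridge] <= straggler_max)) {
        merged <- c(merged, list(c(hi * bin_height, (j - 1L) * bin_height)))
        i <- j
        while (i <= n && histogram[i] == 0L) i <- i + 1L
        hi <- i - 1L
        extended <- TRUE
      }
    }
    if (!extended) break
  }

  y_low <- (lo - 1L) * bin_height
  y_high <- min(hi * bin_height, height)
  structure(list(y_low = y_low, y_high = y_high, bin_height = bin_height,
                 merged_gaps = merged),
            class = "scratch_band")
}

#' @export
print.scratch_band <- function(x, ...) {
  cat(sprintf("scratch_band: rows [%d, %d) (%d px high), %d merged gap(s)\n",
              x$y_low, x$y_high, x$y_high - x$y_low, length(x$merged_gaps)))
  invisible(x)
}

#' Count nuclei inside and outside the scratch band
#'
#' Classification is by centroid: a nucleus is inside when
#' `y_low <= centroid_row < y_high` (half-open, so a centroid exactly on
#' `y_high` is outside).
#'
#' @param nuclei Feature data frame for one frame.
#' @param band A `scratch_band`.
#' @return `c(inside = , outside = )` integer counts.
#' @export
count_in_out <- function(nuclei, band) {
  stopifnot(inherits(band, "scratch_band"))
  if (is.null(nuclei) || nrow(nuclei) == 0L) {
    return(c(inside = 0L, outside = 0L))
  }
  inside <- sum(nuclei$centroid_row >= band$y_low &
                  nuclei$centroid_row < band$y_high)
  c(inside = as.integer(inside), outside = as.integer(nrow(nuclei) - inside))
}

#' Build the per-well infiltration time series
#'
#' The band is determined once, from the first frame, and held fixed for
#' the whole series; counts at frame `k` are taken at time
#' `k * interval_min`.
#'
#' @param per_frame_nuclei List of per-frame feature data frames
#'   (chronological, frame 0 first).
#' @param band A `scratch_band` detected at frame 0.
#' @param interval_min Minutes between consecutive frames.
#' @param well_id Well identifier carried into the series.
#' @return An `infiltration_series`: `well_id`, `times` (minutes, starting
#'   at 0), `inside`, `outside` (integer counts per timepoint).
#' @export
build_infiltration_series <- function(per_frame_nuclei, band, interval_min,
                                      well_id = "well") {
  stopifnot(length(per_frame_nuclei) >= 2L, interval_min > 0)
  counts <- vapply(per_frame_nuclei, count_in_out, integer(2L), band = band)
  infiltration_series(
    well_id = well_id,
    times = (seq_along(per_frame_nuclei) - 1) * interval_min,
    inside = counts["inside", ], outside = counts["outside", ])
}

#' Construct an infiltration series
#'
#' @param well_id Well identifier.
#' @param times Strictly increasing times in minutes, starting at 0.
#' @param inside,outside Non-negative integer counts per timepoint.
#' @return An object of class `infiltration_series`.
#' @export
infiltration_series <- function(well_id, times, inside, outside) {
  stopifnot(length(times) == length(inside),
            length(inside) == length(outside))
  if (length(times) > 0L) {
    stopifnot(times[1L] == 0, all(diff(times) > 0),
              all(inside >= 0), all(outside >= 0))
  }
  structure(list(well_id = well_id, times = as.numeric(times),
                 inside = as.integer(round(inside)),
                 outside = as.integer(round(outside))),
            class = "infiltration_series")
}

#' @export
print.infiltration_series <- function(x, ...) {
  cat(sprintf(
    "infiltration_series %s: %d timepoints over %g min, inside %d -> %d\n",
    x$well_id, length(x$times), max(x$times),
    x$inside[1L], x$inside[length(x$inside)]))
  invisible(x)
}
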