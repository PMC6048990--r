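# Gaussian smoothing with the filter radius capped to the image size
# (odd, no larger than either dimension) and replicate boundary handling.
gaussian_smooth <- function(image, sigma) {
  r <- 2L * ceiling(3 * sigma) + 1L
  r <- min(r, nrow(image), ncol(image))
  if (r %% 2L == 0L) r <- r - 1L
  if (r < 3L) return(image)
  EBImage::gblur(image, sigma = sigma, radius = r, boundary = "replicate")
}

#' Estimate the illumination function of a frame
#'
#' Uneven illumination is modelled as a smooth additive background. The
#' estimate is the per-block minimum intensity image (blocks of
#' `block_size` x `block_size` pixels; partial blocks at the right/bottom
#' edges are allowed), upsampled back to full resolution by nearest
#' neighbour and smoothed with a Gaussian filter of standard deviation
#' `sigma` (default: one block).
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param block_size Block side in pixels, >= 2 and no larger than either
#'   image dimension.
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @return Matrix of the same shape as `image`; never exceeds `max(image)`.
#' @export
compute_illumination_function <- function(image, block_size, sigma = block_size) {
  block_size <- as.integer(block_size)
  if (block_size < 2L) stop("block_size must be >= 2", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  if (block_size > h || block_size > w) {
    stop("validation error: block_size (", block_size,
         ") exceeds an image dimension (", h, " x ", w, ")", call. = FALSE)
  }
  row_block <- (seq_len(h) - 1L) %/% block_size + 1L
  col_block <- (seq_len(w) - 1L) %/% block_size + 1L
  n_rb <- max(row_block); n_cb <- max(col_block)
  mins <- matrix(Inf, n_rb, n_cb)
  for (bi in seq_len(n_rb)) {
    rows <- which(row_block == bi)
    for (bj in seq_len(n_cb)) {
      mins[bi, bj] <- min(image[rows, which(col_block == bj)])
    }
  }
  upsampled <- mins[row_block, col_block, drop = FALSE]
  smoothed <- gaussian_smooth(upsampled, sigma)
  pmin(smoothed, max(image))
}

#' Subtract an illumination function from a raw frame
#'
#' Elementwise `max(image - illumination, 0)`: the corrected frame keeps the
#' contrast between stained nuclei and background and is clamped at zero.
#'
#' @param image,illumination Numeric matrices of identical shape.
#' @return The corrected frame.
#' @export
subtract_background <- function(image, illumination) {
  if (!identical(dim(image), dim(illumination))) {
    stop("validation error: image and illumination shapes differ", call. = FALSE)
  }
  pmax(image - illumination, 0)
}

#' Global Otsu threshold
#'
#' Builds a 256-bin histogram over the observed intensity range and returns
#' the bin-edge threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the split; pixels strictly above the
#' threshold are foreground. Ties go to the lowest maximizing threshold.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param n_bins Number of histogram bins (256 by default).
#' @return Scalar threshold on the intensity scale of `image`.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    stop("degenerate input: constant image has no Otsu threshold", call. = FALSE)
  }
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w0 <- cumsum(counts)
  sum0 <- cumsum(counts * mids)
  total <- w0[n_bins]; total_sum <- sum0[n_bins]
  # candidate k = split after bin k (threshold at the upper edge of bin k)
  k <- seq_len(n_bins - 1L)
  w1 <- total - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  mu0 <- sum0[k][valid] / w0[k][valid]
  mu1 <- (total_sum - sum0[k][valid]) / w1[valid]
  sigma_b[valid] <- (w0[k][valid] / total) * (w1[valid] / total) * (mu0 - mu1)^2
  best <- which.max(sigma_b)
  lo + best * (hi - lo) / n_bins
}

# Split an integer-valued matrix into 4-connected components of equal
# positive values, by iterative minimum-index propagation (vectorized; the
# iteration count is bounded by the geodesic diameter of the largest
# object, small for nucleus-sized blobs). Returns an integer label matrix
# with consecutive labels 1..n in column-major order of first appearance.
split_labels_4conn <- function(values) {
  h <- nrow(values); w <- ncol(values)
  fg <- values > 0L
  if (!any(fg)) return(matrix(0L, h, w))
  lab <- matrix(Inf, h, w)
  lab[fg] <- which(fg)
  same_v <- values[-h, , drop = FALSE] == values[-1L, , drop = FALSE] &
    fg[-h, , drop = FALSE] & fg[-1L, , drop = FALSE]
  same_h <- values[, -w, drop = FALSE] == values[, -1L, drop = FALSE] &
    fg[, -w, drop = FALSE] & fg[, -1L, drop = FALSE]
  pull <- function(lab, tgt_idx, src_idx, same, horizontal) {
    if (horizontal) {
      tgt <- lab[, tgt_idx, drop = FALSE]; src <- lab[, src_idx, drop = FALSE]
    } else {
      tgt <- lab[tgt_idx, , drop = FALSE]; src <- lab[src_idx, , drop = FALSE]
    }
    tgt[same] <- pmin(tgt[same], src[same])
    if (horizontal) lab[, tgt_idx] <- tgt else lab[tgt_idx, ] <- tgt
    lab
  }
  repeat {
    prev <- lab
    lab <- pull(lab, -1L, -h, same_v, FALSE)   # from the row above
    lab <- pull(lab, -h, -1L, same_v, FALSE)   # from the row below
    lab <- pull(lab, -1L, -w, same_h, TRUE)    # from the column left
    lab <- pull(lab, -w, -1L, same_h, TRUE)    # from the column right
    if (identical(lab, prev)) break
  }
  out <- matrix(0L, h, w)
  out[fg] <- match(lab[fg], sort(unique(lab[fg])))
  out
}

# 4-connected component labelling of a logical mask.
label_components <- function(mask) {
  split_labels_4conn(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}

#' Identify nuclei in an illumination-corrected frame
#'
#' Foreground is the global Otsu mask of the corrected frame. Touching
#' nuclei are declumped with an intensity watershed: nuclei are brighter
#' towards their interior than their edges, so the smoothed intensity
#' surface (Gaussian, sigma = `min_diameter / 2`) has one regional maximum
#' per nucleus and the watershed splits merged masks along the intensity
#' valleys. Components whose equivalent diameter `2 * sqrt(area / pi)`
#' falls outside `[min_diameter, max_diameter]` (inclusive) are removed and
#' the survivors relabelled consecutively. Objects touching the image
#' border are kept.
#'
#' @param corrected Illumination-corrected frame (numeric matrix).
#' @param params A [segmentation_params()].
#' @return An object map: `list(labels = <integer matrix>, n_objects)`, where
#'   0 denotes background. A constant frame yields zero objects.
#' @export
identify_primary_objects <- function(corrected, params) {
  stopifnot(inherits(params, "segmentation_params"))
  empty <- list(labels = matrix(0L, nrow(corrected), ncol(corrected)),
                n_objects = 0L)
  if (max(corrected) <= min(corrected)) return(empty)
  thr <- otsu_threshold(corrected)
  mask <- corrected > thr
  if (!any(mask)) return(empty)

  sm <- gaussian_smooth(corrected, params$min_diameter / 2)
  surface <- (sm - min(sm)) / max(sm - min(sm) + .Machine$double.eps)
  surface[!mask] <- 0
  # watershed tolerance: minima shallower than 5% of the intensity range are
  # not treated as separate nuclei; ext approximates the minimum seed spacing
  ws <- EBImage::watershed(surface, tolerance = 0.05,
                           ext = max(1L, round(params$min_diameter / 2)))
  ws <- matrix(as.integer(ws), nrow(corrected), ncol(corrected))

  # split watershed regions into 4-connected pieces so every label is one
  # 4-connected component, then apply the diameter filter
  pieces <- split_labels_4conn(ws)
  n_pieces <- max(pieces)
  if (n_pieces == 0L) return(empty)
  areas <- tabulate(pieces[pieces > 0L], nbins = n_pieces)
  eq_diam <- 2 * sqrt(areas / pi)
  keep <- eq_diam >= params$min_diameter & eq_diam <= params$max_diameter
  fgp <- pieces > 0L
  pieces[fgp][!keep[pieces[fgp]]] <- 0L
  n_kept <- sum(keep)
  if (n_kept == 0L) return(empty)
  fgp <- pieces > 0L
  pieces[fgp] <- match(pieces[fgp], which(keep))
  list(labels = pieces, n_objects = as.integer(n_kept))
}

#' Extract per-nucleus features from an object map
#'
#' Centroids are unweighted means of member-pixel coordinates, 0-based with
#' row 0 at the image top; area is the pixel count; eccentricity comes from
#' the second central moments (0 for a disc, towards 1 for elongated
#' objects); mean intensity is taken over the corrected frame.
#'
#' @param objects Object map from [identify_primary_objects()].
#' @param corrected The corrected frame the map was computed from.
#' @param frame_index 0-based temporal index stored with each record.
#' @return A data frame with one row per object: `frame`, `object_id`,
#'   `centroid_row`, `centroid_col`, `area_px`, `eccentricity`,
#'   `mean_intensity`.
#' @export
extract_features <- function(objects, corrected, frame_index = 0L) {
  n <- objects$n_objects
  empty <- data.frame(frame = integer(), object_id = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      area_px = integer(), eccentricity = numeric(),
                      mean_intensity = numeric())
  if (n == 0L) return(empty)
  labels <- objects$labels
  idx <- which(labels > 0L)
  lab <- labels[idx]
  h <- nrow(labels)
  rows0 <- ((idx - 1L) %% h)           # 0-based row
  cols0 <- ((idx - 1L) %/% h)          # 0-based col
  area <- tabulate(lab, nbins = n)
  cr <- as.numeric(tapply(rows0, lab, mean))
  cc <- as.numeric(tapply(cols0, lab, mean))
  mi <- as.numeric(tapply(corrected[idx], lab, mean))
  # central second moments -> eigenvalues of the coordinate covariance
  dr <- rows0 - cr[lab]; dc <- cols0 - cc[lab]
  mu20 <- as.numeric(tapply(dr * dr, lab, mean))
  mu02 <- as.numeric(tapply(dc * dc, lab, mean))
  mu11 <- as.numeric(tapply(dr * dc, lab, mean))
  common <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  data.frame(frame = as.integer(frame_index), object_id = seq_len(n),
             centroid_row = cr, centroid_col = cc, area_px = as.integer(area),
             eccentricity = ecc, mean_intensity = mi)
}

#' Segment one frame end to end
#'
#' Convenience wrapper: illumination estimation, subtraction, Otsu
#' thresholding with watershed declumping and diameter filtering, feature
#' extraction.
#'
#' @inheritParams extract_features
#' @param image Raw grayscale frame.
#' @param params A [segmentation_params()].
#' @return As [extract_features()].
#' @export
segment_frame <- function(image, params, frame_index = 0L) {
  illum <- compute_illumination_function(image, params$block_size)
  corrected <- subtract_background(image, illum)
  objects <- identify_primary_objects(corrected, params)
  extract_features(objects, corrected, frame_index)
}

#' Segment every frame of an image stack
#'
#' The pipeline is applied independently per frame with identical
#' parameters; the result is deterministic given the inputs. All-background
#' frames yield empty feature tables, not errors.
#'
#' @param stack An [image_stack()].
#' @param params A [segmentation_params()].
#' @return A list, one element per frame, each a feature data frame as
#'   returned by [extract_features()].
#' @export
segment_series <- function(stack, params) {
  stopifnot(inherits(stack, "image_stack"))
  lapply(seq_along(stack$frames), function(k) {
    tryCatch(
      segment_frame(stack$frames[[k]], params, frame_index = k - 1L),
      error = function(e) {
        stop("frame ", k - 1L, ": ", conditionMessage(e), call. = FALSE)
      })
  })
}
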