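#' Specification of a synthetic scratch-assay plate
#'
#' Describes a ground-truthed in silico plate emulating a confluent
#' Hoechst-stained epithelial monolayer with a horizontal cell-free
#' scratch band whose infiltration follows a modified Gompertz curve.
#' Defaults mirror a 96-well assay imaged every 20 minutes for 5 hours at
#' low magnification: 600 x 800 px frames, a 200-row band across the
#' middle of the frame (the proportions of a 0.3 mm scratch in a 4x field)
#' and 16 timepoints.
#'
#' @param n_wells Number of wells.
#' @param height,width Frame size in pixels.
#' @param band_low,band_high Scratch band rows, half-open `[low, high)`.
#' @param nucleus_diameter Rendered nucleus diameter in pixels (Gaussian
#'   spots of sigma = diameter / 4).
#' @param density_outside Monolayer density outside the band, nuclei per
#'   pixel^2; must permit non-overlapping placement at the given diameter.
#' @param truth List (length `n_wells`, recycled from one) of generating
#'   Gompertz parameters `list(A, mu_m, lam)` per well.
#' @param times Acquisition times in minutes.
#' @param noise_sd Pixel noise standard deviation, intensity units.
#' @param background Length-2 numeric: additive offset and top-to-bottom
#'   vertical ramp amplitude, intensity units (the ramp exercises the
#'   illumination correction).
#' @param amplitude Peak nucleus intensity above background.
#' @param seed Integer seed; everything derived from the spec is
#'   deterministic given it.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(n_wells = 6L, height = 600L, width = 800L,
                       band_low = 220L, band_high = 420L,
                       nucleus_diameter = 14,
                       density_outside = 1 / 18^2,
                       truth = list(A = 300, mu_m = 2, lam = 30),
                       times = seq(0, 300, by = 20),
                       noise_sd = 40, background = c(400, 1200),
                       amplitude = 12000, seed = 1L) {
  stopifnot(band_low >= 0, band_low < band_high, band_high <= height,
            nucleus_diameter > 0, density_outside > 0, noise_sd >= 0,
            length(background) == 2L, times[1L] == 0, all(diff(times) > 0))
  if (!is.null(truth$A)) truth <- rep(list(truth), n_wells)
  stopifnot(length(truth) == n_wells)
  spacing <- 1 / sqrt(density_outside)
  if (spacing <= nucleus_diameter) {
    stop("validation error: density_outside too high for non-overlapping ",
         "placement at this nucleus diameter; lower the density", call. = FALSE)
  }
  structure(list(n_wells = as.integer(n_wells), height = as.integer(height),
                 width = as.integer(width), band_low = as.integer(band_low),
                 band_high = as.integer(band_high),
                 nucleus_diameter = nucleus_diameter,
                 density_outside = density_outside, truth = truth,
                 times = as.numeric(times), noise_sd = noise_sd,
                 background = as.numeric(background), amplitude = amplitude,
                 seed = as.integer(seed)),
            class = "plate_spec")
}

#' Simulate a Gompertz-driven infiltration count series
#'
#' Drives the modelling stage without images: counts are the model values
#' plus Gaussian noise, rounded and clamped at zero. Deterministic per
#' seed.
#'
#' @param truth Generating parameters `list(A, mu_m, lam)`.
#' @param times Strictly increasing times in minutes starting at 0.
#' @param noise_sd Count noise standard deviation (cells).
#' @param seed Integer seed.
#' @param well_id Identifier carried into the series.
#' @return An `infiltration_series` with attribute `truth`.
#' @export
simulate_count_series <- function(truth, times = seq(0, 300, by = 20),
                                  noise_sd = 0, seed = 1L,
                                  well_id = "sim") {
  stopifnot(noise_sd >= 0, all(diff(times) > 0))
  model <- gompertz(times, truth$A, truth$mu_m, truth$lam)
  set.seed(seed)
  eps <- stats::rnorm(length(times), 0, noise_sd)
  inside <- pmax(0, round(model + if (noise_sd > 0) eps else 0))
  ser <- infiltration_series(well_id, times, inside,
                             outside = rep(0L, length(times)))
  attr(ser, "truth") <- truth
  ser
}

#' Simulate an adverse-effect infiltration series
#'
#' Emulates cytotoxic exposure: a Gompertz rise until `decline_start`
#' minutes, after which counts decay exponentially at `decline_rate` per
#' minute (cell death empties the band and the wound stays unresolved).
#' With `decline_rate = 0` this reduces exactly to
#' [simulate_count_series()].
#'
#' @inheritParams simulate_count_series
#' @param decline_start Minutes at which the decline begins (within the
#'   time range).
#' @param decline_rate Exponential decay rate per minute (>= 0).
#' @return An `infiltration_series` with attribute `truth`.
#' @export
simulate_adverse_series <- function(truth, decline_start = 150,
                                    decline_rate = 0.02,
                                    times = seq(0, 300, by = 20),
                                    noise_sd = 0, seed = 1L,
                                    well_id = "adverse") {
  stopifnot(decline_rate >= 0,
            decline_start >= min(times), decline_start <= max(times))
  model <- gompertz(times, truth$A, truth$mu_m, truth$lam)
  decay <- ifelse(times > decline_start,
                  exp(-decline_rate * (times - decline_start)), 1)
  set.seed(seed)
  eps <- stats::rnorm(length(times), 0, noise_sd)
  inside <- pmax(0, round(model * decay + if (noise_sd > 0) eps else 0))
  ser <- infiltration_series(well_id, times, inside,
                             outside = rep(0L, length(times)))
  attr(ser, "truth") <- truth
  ser
}

#' Render one synthetic fluorescence frame
#'
#' Each nucleus is an isotropic Gaussian spot (sigma = diameter / 4, peak
#' `amplitude` far above background) on a background of a constant offset
#' plus a top-to-bottom vertical intensity ramp plus i.i.d. Gaussian pixel
#' noise. Deterministic per seed.
#'
#' @param positions Two-column matrix of 0-based (row, col) nucleus
#'   centres, all within the frame.
#' @param spec A [plate_spec()] (frame geometry, diameter, background,
#'   noise, amplitude).
#' @param seed Integer seed for the pixel noise.
#' @return Numeric intensity matrix `height x width`, clamped to the
#'   16-bit range.
#' @export
render_frame <- function(positions, spec, seed = 1L) {
  h <- spec$height; w <- spec$width
  ramp <- spec$background[2L] * (seq_len(h) - 1) / max(h - 1, 1)
  img <- matrix(spec$background[1L] + ramp, h, w)
  if (!is.null(positions) && nrow(positions) > 0L) {
    stopifnot(all(positions[, 1L] >= 0), all(positions[, 1L] < h),
              all(positions[, 2L] >= 0), all(positions[, 2L] < w))
    sigma <- spec$nucleus_diameter / 4
    half <- ceiling(4 * sigma)
    for (i in seq_len(nrow(positions))) {
      r0 <- positions[i, 1L]; c0 <- positions[i, 2L]
      rows <- seq2(max(0L, floor(r0 - half)), min(h - 1L, ceiling(r0 + half)))
      cols <- seq2(max(0L, floor(c0 - half)), min(w - 1L, ceiling(c0 + half)))
      spot <- spec$amplitude *
        exp(-(outer((rows - r0)^2, (cols - c0)^2, "+")) / (2 * sigma^2))
      img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] + spot
    }
  }
  if (spec$noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
  }
  pmin(pmax(img, 0), 65535)
}

# Jittered-grid positions covering the rows outside [band_low, band_high),
# with pairwise spacing > diameter. 0-based (row, col).
monolayer_positions <- function(spec) {
  spacing <- 1 / sqrt(spec$density_outside)
  jitter_max <- (spacing - spec$nucleus_diameter) / 2 * 0.95
  grid_r <- seq(spacing / 2, spec$height - spacing / 2, by = spacing)
  grid_c <- seq(spacing / 2, spec$width - spacing / 2, by = spacing)
  pts <- expand.grid(row = grid_r, col = grid_c)
  pts <- pts[pts$row < spec$band_low - spec$nucleus_diameter / 2 |
               pts$row >= spec$band_high + spec$nucleus_diameter / 2, ]
  jr <- stats::runif(nrow(pts), -jitter_max, jitter_max)
  jc <- stats::runif(nrow(pts), -jitter_max, jitter_max)
  cbind(row = pts$row + jr, col = pts$col + jc)
}

# Uniform non-overlapping positions inside the band by dart throwing.
# 0-based (row, col); stops with an error when packing is infeasible.
band_positions <- function(spec, n) {
  if (n == 0L) return(cbind(row = numeric(), col = numeric()))
  d <- spec$nucleus_diameter
  margin <- d / 2
  area <- (spec$band_high - spec$band_low - 2 * margin) *
    (spec$width - 2 * margin)
  if (n * pi * (d / 2)^2 > 0.5 * area) {
    stop("validation error: infeasible packing of ", n,
         " nuclei in the band; lower the density or plateau count",
         call. = FALSE)
  }
  out <- matrix(NA_real_, n, 2L)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n) {
      stop("validation error: could not place non-overlapping nuclei in the band",
           call. = FALSE)
    }
    r <- stats::runif(1, spec$band_low + margin, spec$band_high - margin)
    cc <- stats::runif(1, margin, spec$width - margin)
    if (placed == 0L ||
        min((out[seq_len(placed), 1L] - r)^2 +
              (out[seq_len(placed), 2L] - cc)^2) > d^2) {
      placed <- placed + 1L
      out[placed, ] <- c(r, cc)
    }
  }
  colnames(out) <- c("row", "col")
  out
}

#' Simulate a full on-disk scratch-assay plate
#'
#' Writes, per well, a folder of 16-bit grayscale TIFF frames in
#' consecutive temporal order; a parseable plate index file; and
#' ground-truth tables (per-frame nucleus positions and per-well
#' generating parameters). The monolayer outside the band is fixed across
#' frames; only the population inside the band grows, following
#' `round(gompertz(t))` of each well's truth, with earlier infiltrators
#' retained (placements are a growing prefix of one non-overlapping set).
#'
#' @param spec A [plate_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `index` (path), `truth_params` (data frame),
#'   `truth_positions` (data frame of all planted nuclei),
#'   `well_dirs`.
#' @export
simulate_plate <- function(spec, out_dir) {
  stopifnot(inherits(spec, "plate_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  wells <- sprintf("W%02d", seq_len(spec$n_wells))
  truth_rows <- list()
  pos_rows <- list()
  # segmentation parameters matched to the rendered nucleus size
  min_d <- max(2L, round(spec$nucleus_diameter * 0.45))
  max_d <- round(spec$nucleus_diameter * 2.2)
  index_lines <- c(paste(c("well", "folder", "rotation_deg", "interval_min",
                           "block_size", "min_diameter", "max_diameter"),
                         collapse = "\t"))
  interval <- diff(spec$times)[1L]

  for (wi in seq_len(spec$n_wells)) {
    well <- wells[wi]
    wdir <- file.path(out_dir, well)
    dir.create(wdir, showWarnings = FALSE)
    truth <- spec$truth[[wi]]
    outside_pos <- monolayer_positions(spec)
    n_inside <- pmax(0L, as.integer(round(
      gompertz(spec$times, truth$A, truth$mu_m, truth$lam))))
    inside_all <- band_positions(spec, max(n_inside))
    for (k in seq_along(spec$times)) {
      pos_k <- rbind(outside_pos, inside_all[seq2(1L, n_inside[k]), , drop = FALSE])
      frame_seed <- spec$seed + 7919L * wi + k
      img <- render_frame(pos_k, spec, seed = frame_seed)
      tiff::writeTIFF(round(img) / 65535, file.path(wdir, sprintf("t%02d.tif", k - 1L)),
                      bits.per.sample = 16L, compression = "none")
      pos_rows[[length(pos_rows) + 1L]] <- data.frame(
        well = well, frame = k - 1L,
        row = pos_k[, 1L], col = pos_k[, 2L],
        inside_band = pos_k[, 1L] >= spec$band_low & pos_k[, 1L] < spec$band_high)
    }
    truth_rows[[wi]] <- data.frame(
      well = well, A = truth$A, mu_m = truth$mu_m, lam = truth$lam,
      n_outside = nrow(outside_pos))
    index_lines <- c(index_lines, paste(
      c(well, well, 0, interval, 10, min_d, max_d), collapse = "\t"))
  }

  index_path <- file.path(out_dir, "index.tsv")
  writeLines(index_lines, index_path, useBytes = TRUE)
  truth_params <- do.call(rbind, truth_rows)
  truth_positions <- do.call(rbind, pos_rows)
  utils::write.table(truth_params, file.path(out_dir, "truth_params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth_positions, file.path(out_dir, "truth_positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(index = index_path, truth_params = truth_params,
                 truth_positions = truth_positions,
                 well_dirs = file.path(out_dir, wells),
                 band = c(low = spec$band_low, high = spec$band_high)))
}
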