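# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately use naive loops / direct formulas,
# not the package's code paths.

# Exhaustive Otsu: same 256-bin histogram convention as the implementation,
# but a plain loop over every candidate split, computing class weights and
# means directly.
oracle_otsu <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1L)
  mids <- lo + (0:(n_bins - 1L) + 0.5) * (hi - lo) / n_bins
  best_var <- -Inf; best_k <- NA_integer_
  for (k in 1:(n_bins - 1L)) {
    in0 <- bin < k
    n0 <- sum(in0); n1 <- length(v) - n0
    if (n0 == 0L || n1 == 0L) next
    m0 <- mean(mids[bin[in0] + 1L]); m1 <- mean(mids[bin[!in0] + 1L])
    w0 <- n0 / length(v); w1 <- n1 / length(v)
    s <- w0 * w1 * (m0 - m1)^2
    if (s > best_var + 1e-12) { best_var <- s; best_k <- k }
  }
  lo + best_k * (hi - lo) / n_bins
}

# Plain longest-zero-run maximizer (no merging), tie-break nearest to the
# vertical image centre; returns pixel rows c(y_low, y_high).
oracle_longest_zero_run <- function(histogram, bin_height, height) {
  n <- length(histogram)
  best_len <- 0L; best <- NULL
  for (s in 1:n) {
    if (histogram[s] != 0L) next
    e <- s
    while (e < n && histogram[e + 1L] == 0L) e <- e + 1L
    len <- e - s + 1L
    if (len > best_len) {
      best_len <- len; best <- list(c(s, e))
    } else if (len == best_len) {
      best <- c(best, list(c(s, e)))
    }
    if (e == n) break
  }
  runs <- unique(best)
  if (length(runs) > 1L) {
    centre <- height / 2
    d <- vapply(runs, function(r)
      abs(((r[1L] + r[2L]) / 2 - 0.5) * bin_height - centre), numeric(1L))
    runs <- runs[order(d)]
  }
  r <- runs[[1L]]
  c((r[1L] - 1L) * bin_height, min(r[2L] * bin_height, height))
}

# Per-point in/out classification by explicit loop.
oracle_count_in_out <- function(rows, y_low, y_high) {
  inside <- 0L
  for (r in rows) if (r >= y_low && r < y_high) inside <- inside + 1L
  c(inside = inside, outside = length(rows) - inside)
}

# Random histogram guaranteed to contain at least one zero bin.
random_gap_histogram <- function(n_bins) {
  h <- stats::rpois(n_bins, 1.2)
  if (!any(h == 0L)) h[sample.int(n_bins, 1L)] <- 0L
  as.integer(h)
}

# A filled disc as a logical matrix (1-based centre, pixel-centre test).
make_disc <- function(h, w, cr, cc, radius) {
  rr <- matrix(seq_len(h), h, w)
  ccm <- matrix(rep(seq_len(w), each = h), h, w)
  (rr - cr)^2 + (ccm - cc)^2 <= radius^2
}

# Write a minimal well folder of TIFF frames; returns the folder.
write_tiny_well <- function(dir, frames) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(frames)) {
    tiff::writeTIFF(frames[[k]] / 65535,
                    file.path(dir, sprintf("t%02d.tif", k - 1L)),
                    bits.per.sample = 16L, compression = "none")
  }
  dir
}

# Zip a directory (stored relative to its parent) using the Python stdlib.
make_zip <- function(dir, zipfile) {
  script <- sprintf(
    "import zipfile, os, sys\nroot=%s\nzf=zipfile.ZipFile(%s,'w')\nfor dp,_,fs in os.walk(root):\n    for f in sorted(fs):\n        p=os.path.join(dp,f)\n        zf.write(p, os.path.relpath(p, os.path.dirname(root)))\nzf.close()\n",
    deparse(dir), deparse(zipfile))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf)
  stopifnot(status == 0L)
  zipfile
}

# Small plate spec used by the pipeline tests: 240 x 320 px frames, 8
# timepoints, modest counts, so a 2-well plate segments in seconds.
tiny_plate_spec <- function(n_wells = 2L, seed = 101L,
                            truth = list(A = 60, mu_m = 1, lam = 20)) {
  plate_spec(n_wells = n_wells, height = 240L, width = 320L,
             band_low = 90L, band_high = 170L, nucleus_diameter = 12,
             density_outside = 1 / 16^2, truth = truth,
             times = seq(0, 140, by = 20), noise_sd = 30,
             background = c(300, 800), amplitude = 10000, seed = seed)
}

# Index text for a one-well plate, reused across parse tests.
canonical_index_lines <- c(
  "well\tfolder\trotation_deg\tinterval_min\tblock_size\tmin_diameter\tmax_diameter",
  "A01\tA01\t0\t20\t10\t8\t25")
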