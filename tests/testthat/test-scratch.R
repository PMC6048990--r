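test_that("rotation: identity, exact 90-degree permutation, and 4x90 closure", {
  set.seed(7)
  st <- image_stack(list(matrix(runif(30 * 40), 30, 40),
                         matrix(runif(30 * 40), 30, 40)))
  expect_identical(rotate_stack(st, 0), st)
  expect_identical(rotate_stack(st, 360), st)

  # single bright pixel at (row 0, col 0) of an H x W frame lands at
  # (row 0, col H-1) after a clockwise quarter turn
  m <- matrix(0, 30, 40); m[1, 1] <- 9
  r <- rotate_stack(image_stack(list(m, m)), 90)
  expect_equal(dim(r$frames[[1L]]), c(40L, 30L))
  expect_equal(which(r$frames[[1L]] == 9, arr.ind = TRUE)[1, ],
               c(row = 1L, col = 30L))

  r4 <- st
  for (i in 1:4) r4 <- rotate_stack(r4, 90)
  expect_identical(r4$frames, st$frames)
})

test_that("90-degree rotation agrees with the brute-force index permutation", {
  set.seed(8)
  m <- matrix(runif(15 * 22), 15, 22)
  r <- scratchkin:::rotate_frame(m, 90)
  h <- nrow(m)
  for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r))) {
    expect_identical(r[i, j], m[h + 1L - j, i])
  }
})

test_that("arbitrary-angle rotation preserves frame content geometry", {
  m <- matrix(0, 40, 60); m[20, 30] <- 100   # near-centre bright pixel
  r <- scratchkin:::rotate_frame(m, 30)
  expect_true(all(dim(r) >= dim(m) * c(cos(pi / 6), cos(pi / 6))))
  expect_gt(max(r), 20)            # mass survives interpolation
  expect_true(all(r >= 0))
})

test_that("y_frequency bins by the half-open convention and conserves counts", {
  expect_identical(y_frequency(data.frame(centroid_row = numeric()), 100, 10),
                   integer(10))
  # a centroid exactly at bin_height falls in bin 1, not bin 0
  one <- data.frame(centroid_row = 10)
  h <- y_frequency(one, 100, 10)
  expect_identical(h, c(0L, 1L, rep(0L, 8L)))

  set.seed(13)
  nuc <- data.frame(centroid_row = runif(200, 0, 99.9))
  hh <- y_frequency(nuc, 100, 7)
  expect_length(hh, ceiling(100 / 7))
  expect_equal(sum(hh), 200L)
})

test_that("band detection finds the largest cell-free area", {
  # nuclei fill rows [0,200) and [400,600); gap must be [200,400)
  set.seed(14)
  nuc <- data.frame(centroid_row = c(runif(300, 0, 199), runif(300, 400, 599)))
  hist <- y_frequency(nuc, 600, 10)
  band <- detect_scratch_band(hist, 10, 600, merge_span_bins = 0L,
                              straggler_max = 0L)
  expect_equal(c(band$y_low, band$y_high), c(200, 400))
  expect_equal(c(band$y_low, band$y_high),
               unname(oracle_longest_zero_run(hist, 10, 600)))

  # a single zero bin is the only candidate
  h1 <- c(3L, 0L, 5L)
  b1 <- detect_scratch_band(h1, 10, 30)
  expect_equal(c(b1$y_low, b1$y_high), c(10, 20))

  expect_error(detect_scratch_band(c(1L, 2L, 3L), 10, 30), "no cell-free area")
})

test_that("small gaps with stragglers merge into the main band", {
  # zero bins 20-29, one straggler bin 30 (1 cell), zero bins 31-34
  hist <- integer(40)
  hist[1:20] <- 5L
  hist[31] <- 1L          # 1-based bin 31 = spec bin index 30
  hist[36:40] <- 5L
  band <- detect_scratch_band(hist, 10, 400, merge_span_bins = 2L,
                              straggler_max = 2L)
  expect_equal(band$y_low, 200)   # bins 20..34 (0-based) -> rows [200, 350)
  expect_equal(band$y_high, 350)
  expect_length(band$merged_gaps, 1L)
  expect_equal(band$merged_gaps[[1L]], c(300, 310))

  # the same histogram with merging disabled keeps only the largest run
  b0 <- detect_scratch_band(hist, 10, 400, merge_span_bins = 0L,
                            straggler_max = 0L)
  expect_equal(c(b0$y_low, b0$y_high), c(200, 300))

  # a bin with more cells than straggler_max blocks the merge
  hist2 <- hist; hist2[31] <- 3L
  b2 <- detect_scratch_band(hist2, 10, 400, merge_span_bins = 2L,
                            straggler_max = 2L)
  expect_equal(c(b2$y_low, b2$y_high), c(200, 300))
})

test_that("with merging disabled, detection equals the longest-zero-run oracle", {
  set.seed(15)
  for (i in 1:300) {
    hist <- random_gap_histogram(sample(10:60, 1))
    height <- length(hist) * 10L
    band <- detect_scratch_band(hist, 10, height, merge_span_bins = 0L,
                                straggler_max = 0L)
    expect_equal(c(band$y_low, band$y_high),
                 unname(oracle_longest_zero_run(hist, 10, height)))
  }
})

test_that("raising merge thresholds never shrinks the band", {
  set.seed(16)
  for (i in 1:200) {
    hist <- random_gap_histogram(40)
    b00 <- detect_scratch_band(hist, 10, 400, 0L, 0L)
    b22 <- detect_scratch_band(hist, 10, 400, 2L, 2L)
    b43 <- detect_scratch_band(hist, 10, 400, 4L, 3L)
    expect_lte(b00$y_high - b00$y_low, b22$y_high - b22$y_low)
    expect_lte(b22$y_high - b22$y_low, b43$y_high - b43$y_low)
    expect_gte(b00$y_low, b22$y_low)
    expect_lte(b00$y_high, b22$y_high)
  }
})

test_that("in/out counting is half-open and matches per-point classification", {
  band <- structure(list(y_low = 100, y_high = 200, bin_height = 10,
                         merged_gaps = list()), class = "scratch_band")
  edge <- data.frame(centroid_row = c(100, 200, 199.999, 99.999))
  cnt <- count_in_out(edge, band)
  expect_equal(cnt[["inside"]], 2L)   # 100 and 199.999
  expect_equal(cnt[["outside"]], 2L)  # 200 and 99.999

  set.seed(17)
  for (i in 1:50) {
    rows <- runif(sample(1:80, 1), 0, 300)
    got <- count_in_out(data.frame(centroid_row = rows), band)
    expect_identical(got, oracle_count_in_out(rows, 100, 200))
  }
  expect_identical(count_in_out(data.frame(centroid_row = numeric()), band),
                   c(inside = 0L, outside = 0L))
})

test_that("infiltration series conserves totals and uses the acquisition clock", {
  band <- structure(list(y_low = 50, y_high = 150, bin_height = 10,
                         merged_gaps = list()), class = "scratch_band")
  set.seed(18)
  per_frame <- lapply(1:16, function(k)
    data.frame(centroid_row = runif(30 + k, 0, 200)))
  ser <- build_infiltration_series(per_frame, band, 20, "A01")
  expect_s3_class(ser, "infiltration_series")
  expect_equal(ser$times, seq(0, 300, by = 20))
  expect_equal(ser$inside + ser$outside,
               vapply(per_frame, nrow, integer(1L)))

  same <- lapply(1:5, function(k) per_frame[[1L]])
  ser2 <- build_infiltration_series(same, band, 20)
  expect_equal(length(unique(ser2$inside)), 1L)
})

test_that("series built from ground-truth centroids equals the planted counts", {
  spec <- tiny_plate_spec(n_wells = 1L)
  td <- tempfile("plate_")
  sim <- simulate_plate(spec, td)
  pos <- sim$truth_positions
  band <- structure(list(y_low = spec$band_low, y_high = spec$band_high,
                         bin_height = 10, merged_gaps = list()),
                    class = "scratch_band")
  per_frame <- lapply(sort(unique(pos$frame)), function(k)
    data.frame(centroid_row = pos$row[pos$frame == k]))
  ser <- build_infiltration_series(per_frame, band, 20, "W01")
  truth <- sim$truth_params[1, ]
  expect_equal(ser$inside,
               as.integer(round(gompertz(ser$times, truth$A, truth$mu_m,
                                         truth$lam))))
})
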