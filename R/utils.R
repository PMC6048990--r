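# Integer sequence that is empty when from > to (unlike base `:`).
seq2 <- function(from, to) {
  if (from > to) integer() else seq.int(from, to)
}

rbind_rows <- function(lst, prototype) {
  if (length(lst) == 0L) return(prototype)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# Row-per-record table builders shared by the pipeline stages and
# write_results(), so both paths serialize identically.
counts_table <- function(series_list) {
  rbind_rows(lapply(series_list, function(s) {
    data.frame(well = s$well_id, frame = seq_along(s$times) - 1L,
               time_min = s$times, inside = s$inside, outside = s$outside,
               total = s$inside + s$outside)
  }), data.frame(well = character(), frame = integer(), time_min = numeric(),
                 inside = integer(), outside = integer(), total = integer()))
}

bands_table <- function(bands_list) {
  rbind_rows(lapply(names(bands_list), function(w) {
    b <- bands_list[[w]]
    data.frame(well = w, y_low = b$y_low, y_high = b$y_high,
               bin_height = b$bin_height,
               n_merged_gaps = length(b$merged_gaps))
  }), data.frame(well = character(), y_low = integer(), y_high = integer(),
                 bin_height = integer(), n_merged_gaps = integer()))
}

params_table <- function(fits_list) {
  rbind_rows(lapply(fits_list, function(f) {
    data.frame(well = f$well_id, A = f$params$A, mu_m = f$params$mu_m,
               lambda = f$params$lam, r_squared = f$r_squared, rmse = f$rmse,
               converged = f$converged, flagged = f$flagged)
  }), data.frame(well = character(), A = numeric(), mu_m = numeric(),
                 lambda = numeric(), r_squared = numeric(), rmse = numeric(),
                 converged = logical(), flagged = logical()))
}
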