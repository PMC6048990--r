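# Shared TSV serializers: every stage writes through these, so chained
# stage-wise runs and a single run_pipeline() produce byte-identical tables.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

features_path <- function(out_dir, well) file.path(out_dir, sprintf("features_%s.tsv", well))

included_records <- function(records) {
  records[vapply(records, function(r) r$included, logical(1L))]
}

#' Segment every included well of a plate
#'
#' Stage 1 of the pipeline: load each well's TIFF series, rotate it to
#' horizontal-scratch orientation, segment every frame, and write one
#' `features_<well>.tsv` per well plus a `stack_info.tsv` with the frame
#' geometry (needed downstream for band detection).
#'
#' @param index_path Plate index file (see [parse_index()]).
#' @param root Directory the index's well folders live in.
#' @param out_dir Output directory, created if needed.
#' @param excluded Optional character vector of well ids to skip.
#' @return Invisibly, a list with `features` (named list of per-well
#'   feature tables), `info` (stack geometry data frame), `failures`
#'   (named character vector of per-well error messages).
#' @export
pipeline_segment <- function(index_path, root = dirname(index_path),
                             out_dir, excluded = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- filter_index(parse_index(index_path), excluded)
  features <- list()
  info <- list()
  failures <- character()
  for (rec in included_records(records)) {
    res <- tryCatch({
      stack <- load_stack(rec, root)
      stack <- rotate_stack(stack, rec$rotation_deg)
      per_frame <- segment_series(stack, rec$seg_params)
      feats <- do.call(rbind, per_frame)
      write_tsv(feats, features_path(out_dir, rec$well_id))
      list(feats = per_frame,
           info = data.frame(well = rec$well_id,
                             n_frames = length(stack$frames),
                             height = stack$height, width = stack$width))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[rec$well_id] <- conditionMessage(res)
      message("well ", rec$well_id, " failed in segmentation: ",
              conditionMessage(res))
    } else {
      features[[rec$well_id]] <- res$feats
      info[[rec$well_id]] <- res$info
    }
  }
  info_df <- if (length(info)) do.call(rbind, info) else
    data.frame(well = character(), n_frames = integer(),
               height = integer(), width = integer())
  write_tsv(info_df, file.path(out_dir, "stack_info.tsv"))
  invisible(list(features = features, info = info_df, failures = failures))
}

#' Detect scratch bands and count infiltration
#'
#' Stage 2: for each segmented well, build the first-frame cell-frequency
#' histogram, detect the scratch band (held fixed for the series), count
#' nuclei inside/outside per frame, and write `counts.tsv` and
#' `bands.tsv`. The histogram bin height defaults to the well's
#' `min_diameter` (roughly one cell per bin).
#'
#' @inheritParams pipeline_segment
#' @param bin_height Histogram bin height in pixel rows; `NULL` uses each
#'   well's `min_diameter`.
#' @param merge_span_bins,straggler_max Small-gap merge thresholds, see
#'   [detect_scratch_band()].
#' @return Invisibly, a list with `series` (named list of
#'   `infiltration_series`), `bands` (named list of `scratch_band`),
#'   `warnings`, `failures`.
#' @export
pipeline_count <- function(index_path, out_dir, excluded = character(),
                           bin_height = NULL, merge_span_bins = 2L,
                           straggler_max = 2L) {
  records <- filter_index(parse_index(index_path), excluded)
  info <- read_tsv(file.path(out_dir, "stack_info.tsv"))
  series <- list()
  bands <- list()
  warns <- character()
  failures <- character()
  for (rec in included_records(records)) {
    fp <- features_path(out_dir, rec$well_id)
    if (!file.exists(fp) || !rec$well_id %in% info$well) next
    res <- tryCatch({
      feats <- read_tsv(fp)
      geom <- info[info$well == rec$well_id, ]
      per_frame <- lapply(seq_len(geom$n_frames) - 1L,
                          function(k) feats[feats$frame == k, , drop = FALSE])
      bh <- if (is.null(bin_height)) rec$seg_params$min_diameter else bin_height
      hist <- y_frequency(per_frame[[1L]], geom$height, bh)
      band <- detect_scratch_band(hist, bh, geom$height,
                                  merge_span_bins = merge_span_bins,
                                  straggler_max = straggler_max)
      if (band$y_high - band$y_low < 2 * rec$seg_params$max_diameter) {
        w <- paste0("well ", rec$well_id, ": detected band is only ",
                    band$y_high - band$y_low,
                    " px high (< 2 x max_diameter); likely detection failure")
        warning(w, call. = FALSE)
        warns <- c(warns, w)
      }
      list(series = build_infiltration_series(per_frame, band,
                                              rec$interval_min, rec$well_id),
           band = band)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[rec$well_id] <- conditionMessage(res)
      message("well ", rec$well_id, " failed in counting: ",
              conditionMessage(res))
    } else {
      series[[rec$well_id]] <- res$series
      bands[[rec$well_id]] <- res$band
    }
  }
  write_tsv(counts_table(series), file.path(out_dir, "counts.tsv"))
  write_tsv(bands_table(bands), file.path(out_dir, "bands.tsv"))
  invisible(list(series = series, bands = bands, warnings = warns,
                 failures = failures))
}

#' Fit re-epithelialization kinetics for every counted well
#'
#' Stage 3: read `counts.tsv`, fit the modified Gompertz model per well,
#' write `parameters.tsv` and a per-well PNG of measured points with the
#' fitted curve.
#'
#' @inheritParams pipeline_count
#' @param r2_threshold Flagging threshold on R-squared (default 0.9).
#' @return Invisibly, a named list of `kinetic_fit` objects.
#' @export
pipeline_fit <- function(index_path, out_dir, excluded = character(),
                         r2_threshold = 0.9) {
  records <- filter_index(parse_index(index_path), excluded)
  counts <- read_tsv(file.path(out_dir, "counts.tsv"))
  fits <- list()
  for (rec in included_records(records)) {
    sub <- counts[counts$well == rec$well_id, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ser <- infiltration_series(rec$well_id, sub$time_min, sub$inside,
                               sub$outside)
    fit <- fit_gompertz(ser, r2_threshold = r2_threshold)
    fits[[rec$well_id]] <- fit
    plot_fit_png(ser, fit, file.path(out_dir,
                                     sprintf("curve_%s.png", rec$well_id)))
  }
  write_tsv(params_table(fits), file.path(out_dir, "parameters.tsv"))
  invisible(fits)
}

# Measured counts + fitted Gompertz curve for one well, as a PNG.
plot_fit_png <- function(series, fit, path) {
  grDevices::png(path, width = 700, height = 500)
  on.exit(grDevices::dev.off())
  graphics::plot(series$times, series$inside, pch = 19,
                 xlab = "time (min)", ylab = "cells inside scratch",
                 main = sprintf("%s%s", series$well_id,
                                if (isTRUE(fit$flagged)) "  [FLAGGED]" else ""))
  if (all(is.finite(fit$fitted))) {
    tt <- seq(min(series$times), max(series$times), length.out = 200)
    graphics::lines(tt, gompertz(tt, fit$params$A, fit$params$mu_m,
                                 fit$params$lam), col = "firebrick", lwd = 2)
    graphics::legend("bottomright", bty = "n", legend = c(
      sprintf("A = %.1f cells", fit$params$A),
      sprintf("mu_m = %.3f cells/min", fit$params$mu_m),
      sprintf("lambda = %.1f min", fit$params$lam),
      sprintf("R2 = %.3f, RMSE = %.2f", fit$r_squared, fit$rmse)))
  }
  invisible(path)
}

#' Write the static HTML plate report
#'
#' Stage 4: one self-contained page with the per-well kinetic parameter
#' table, detected band geometry, flags, and the fitted-curve images.
#'
#' @param out_dir Directory holding the stage outputs.
#' @return Invisibly, the report path.
#' @export
pipeline_report <- function(out_dir) {
  params <- read_tsv(file.path(out_dir, "parameters.tsv"))
  bands <- read_tsv(file.path(out_dir, "bands.tsv"))
  html_table <- function(df) {
    if (nrow(df) == 0L) return("<p>(no wells)</p>")
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(x) signif(x, 5))
    paste0("<table border='1' cellpadding='4' cellspacing='0'>\n<tr>",
           paste0("<th>", names(df), "</th>", collapse = ""), "</tr>\n",
           paste(apply(df, 1L, function(r) {
             paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
           }), collapse = "\n"), "\n</table>")
  }
  imgs <- if (nrow(params) > 0L) paste(sprintf(
    "<h3>%s</h3><img src='curve_%s.png' width='560'>",
    params$well, params$well), collapse = "\n") else ""
  flagged <- params$well[params$flagged]
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'>",
    "<title>Scratch-assay kinetics report</title></head><body>\n",
    "<h1>Scratch-assay re-epithelialization kinetics</h1>\n",
    "<h2>Kinetic parameters</h2>\n", html_table(params), "\n",
    if (length(flagged)) paste0(
      "<p><b>Flagged for inspection (R&sup2; &lt; threshold or no convergence):</b> ",
      paste(flagged, collapse = ", "), "</p>\n") else
        "<p>No wells flagged.</p>\n",
    "<h2>Detected scratch bands</h2>\n", html_table(bands), "\n",
    "<h2>Fitted curves</h2>\n", imgs, "\n</body></html>\n")
  path <- file.path(out_dir, "report.html")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

#' Run the full scratch-assay pipeline on a plate
#'
#' Per included well: load the TIFF series, rotate to horizontal-scratch
#' orientation, segment every frame, detect the scratch band from the
#' first frame, count cells inside/outside over time, fit the modified
#' Gompertz model and flag poor fits. All tabular, graphical and HTML
#' outputs are written to `out_dir`. A failing well is recorded and
#' skipped; the run only errors when the inputs are invalid or every well
#' fails.
#'
#' @param index_path Plate index file.
#' @param root Directory holding the well folders (default: next to the
#'   index).
#' @param out_dir Output directory.
#' @param excluded Character vector of well ids to exclude.
#' @param bin_height,merge_span_bins,straggler_max Band-detection
#'   settings, see [pipeline_count()].
#' @param r2_threshold Fit-flagging threshold (default 0.9).
#' @return A `plate_result`: named per-well entries (`series`, `band`,
#'   `fit`), `warnings`, `failures`, `manifest` (paths written) and
#'   `metadata`.
#' @export
run_pipeline <- function(index_path, root = dirname(index_path), out_dir,
                         excluded = character(), bin_height = NULL,
                         merge_span_bins = 2L, straggler_max = 2L,
                         r2_threshold = 0.9) {
  seg <- pipeline_segment(index_path, root, out_dir, excluded)
  cnt <- pipeline_count(index_path, out_dir, excluded,
                        bin_height = bin_height,
                        merge_span_bins = merge_span_bins,
                        straggler_max = straggler_max)
  fits <- pipeline_fit(index_path, out_dir, excluded,
                       r2_threshold = r2_threshold)
  report <- pipeline_report(out_dir)

  failures <- c(seg$failures, cnt$failures)
  records <- filter_index(parse_index(index_path), excluded)
  n_included <- length(included_records(records))
  if (n_included > 0L && length(fits) == 0L) {
    stop("pipeline error: all ", n_included, " included wells failed",
         call. = FALSE)
  }
  wells <- lapply(names(fits), function(w) {
    list(series = cnt$series[[w]], band = cnt$bands[[w]], fit = fits[[w]])
  })
  names(wells) <- names(fits)
  manifest <- list(
    index = index_path,
    tables = file.path(out_dir, c("stack_info.tsv", "counts.tsv", "bands.tsv",
                                  "parameters.tsv")),
    features = unname(vapply(names(fits), function(w)
      features_path(out_dir, w), character(1L))),
    plots = file.path(out_dir, sprintf("curve_%s.png", names(fits))),
    report = report)
  metadata <- list(
    package_version = as.character(utils::packageVersion("scratchkin")),
    n_wells_included = n_included,
    excluded = as.character(excluded),
    settings = list(bin_height = bin_height,
                    merge_span_bins = merge_span_bins,
                    straggler_max = straggler_max,
                    r2_threshold = r2_threshold))
  jsonlite::write_json(
    list(metadata = metadata, failures = as.list(failures),
         warnings = cnt$warnings,
         manifest = lapply(manifest, as.character)),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  structure(list(wells = wells, warnings = cnt$warnings, failures = failures,
                 manifest = manifest, metadata = metadata),
            class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  cat(sprintf("plate_result: %d well(s), %d flagged, %d failed\n",
              length(x$wells),
              sum(vapply(x$wells, function(w) isTRUE(w$fit$flagged), logical(1L))),
              length(x$failures)))
  invisible(x)
}

#' Write all outputs for an already-computed plate result
#'
#' Re-serialises a `plate_result` (feature tables are not re-derived; the
#' per-well series, bands and fits are) into `out_dir`: counts, bands and
#' parameters TSVs, per-well curve PNGs and the HTML report. Rerunning on
#' the same directory overwrites the previous outputs and yields an
#' identical manifest.
#'
#' @param plate A `plate_result`.
#' @param out_dir Writable output directory.
#' @return The manifest: a named list of written paths.
#' @export
write_results <- function(plate, out_dir) {
  stopifnot(inherits(plate, "plate_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({ f <- file.path(out_dir, ".write_test");
                   file.create(f, showWarnings = FALSE) && file.remove(f) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop("I/O error: output directory not writable: ",
                        out_dir, call. = FALSE)
  series <- lapply(plate$wells, `[[`, "series")
  write_tsv(counts_table(series), file.path(out_dir, "counts.tsv"))
  write_tsv(bands_table(lapply(plate$wells, `[[`, "band")),
            file.path(out_dir, "bands.tsv"))
  fits <- lapply(plate$wells, `[[`, "fit")
  write_tsv(params_table(fits), file.path(out_dir, "parameters.tsv"))
  for (w in names(plate$wells)) {
    plot_fit_png(plate$wells[[w]]$series, plate$wells[[w]]$fit,
                 file.path(out_dir, sprintf("curve_%s.png", w)))
  }
  report <- pipeline_report(out_dir)
  list(tables = file.path(out_dir, c("counts.tsv", "bands.tsv",
                                     "parameters.tsv")),
       plots = if (length(plate$wells))
         file.path(out_dir, sprintf("curve_%s.png", names(plate$wells)))
       else character(),
       report = report)
}
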