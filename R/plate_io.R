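#' Parse a plate index file
#'
#' The index file describes one well per row and drives the whole pipeline.
#' It is tab-separated, UTF-8, with a header line
#' `well<TAB>folder<TAB>rotation_deg<TAB>interval_min<TAB>block_size<TAB>min_diameter<TAB>max_diameter`;
#' lines starting with `#` are ignored. `well`, `folder`, `interval_min`,
#' `min_diameter` and `max_diameter` are mandatory; `rotation_deg` defaults to
#' 0 and `block_size` to 10 when the column is absent.
#'
#' @param index_path Path to the tab-separated index file.
#' @return A list of `well_record` objects, in file order. Each record holds
#'   `well_id`, `source` (folder name or zip member), `rotation_deg`
#'   (clockwise degrees), `interval_min` (minutes between frames),
#'   `seg_params` (see [segmentation_params()]) and `included` (logical,
#'   initially `TRUE`).
#' @seealso [filter_index()], [load_stack()]
#' @export
parse_index <- function(index_path) {
  if (!file.exists(index_path)) {
    stop("index file not found: ", index_path, call. = FALSE)
  }
  lines <- readLines(index_path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("index file is empty", call. = FALSE)

  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  header <- trimws(header)
  mandatory <- c("well", "folder", "interval_min", "min_diameter", "max_diameter")
  missing_cols <- setdiff(mandatory, header)
  if (length(missing_cols) > 0L) {
    stop("index format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  get_field <- function(fields, col, row_num, default = NULL, numeric = TRUE) {
    idx <- match(col, header)
    if (is.na(idx) || idx > length(fields) || !nzchar(trimws(fields[idx]))) {
      return(default)
    }
    val <- trimws(fields[idx])
    if (!numeric) return(val)
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) {
      stop("index parse error at data row ", row_num, ": column '", col,
           "' value '", val, "' is not numeric", call. = FALSE)
    }
    num
  }

  records <- vector("list", length(lines) - 1L)
  for (i in seq_along(records)) {
    fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    well_id <- get_field(fields, "well", i, numeric = FALSE)
    source <- get_field(fields, "folder", i, numeric = FALSE)
    if (is.null(well_id) || is.null(source)) {
      stop("index parse error at data row ", i,
           ": 'well' and 'folder' must be non-empty", call. = FALSE)
    }
    rotation <- get_field(fields, "rotation_deg", i, default = 0)
    interval <- get_field(fields, "interval_min", i)
    block <- get_field(fields, "block_size", i, default = 10)
    min_d <- get_field(fields, "min_diameter", i)
    max_d <- get_field(fields, "max_diameter", i)
    if (is.null(interval) || is.null(min_d) || is.null(max_d)) {
      stop("index parse error at data row ", i,
           ": interval_min, min_diameter and max_diameter are mandatory",
           call. = FALSE)
    }
    records[[i]] <- well_record(
      well_id = well_id, source = source, rotation_deg = rotation,
      interval_min = interval,
      seg_params = segmentation_params(block, min_d, max_d)
    )
  }

  ids <- vapply(records, function(r) r$well_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("index validation error: duplicate well_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  records
}

#' Construct a well record
#'
#' @param well_id Short well identifier (unique within a plate).
#' @param source Folder (relative to the plate root) or zip member holding the
#'   well's image series.
#' @param rotation_deg Clockwise rotation, in degrees, needed to bring the
#'   scratch horizontal.
#' @param interval_min Minutes between consecutive frames; must be positive.
#' @param seg_params A [segmentation_params()] object.
#' @param included Logical; excluded wells are carried through the index but
#'   skipped by the pipeline.
#' @return An object of class `well_record`.
#' @export
well_record <- function(well_id, source, rotation_deg = 0, interval_min,
                        seg_params, included = TRUE) {
  stopifnot(is.character(well_id), length(well_id) == 1L, nzchar(well_id))
  if (!is.finite(rotation_deg)) stop("rotation_deg must be finite", call. = FALSE)
  if (!is.finite(interval_min) || interval_min <= 0) {
    stop("interval_min must be a positive number", call. = FALSE)
  }
  structure(
    list(well_id = well_id, source = source,
         rotation_deg = as.numeric(rotation_deg),
         interval_min = as.numeric(interval_min),
         seg_params = seg_params, included = isTRUE(included)),
    class = "well_record"
  )
}

#' Segmentation parameters for one well
#'
#' @param block_size Side, in pixels, of the blocks over which minimum
#'   intensities are taken when estimating the illumination function
#'   (typical values 5--20).
#' @param min_diameter,max_diameter Accepted range of object equivalent
#'   diameters, in pixels; inclusive on both bounds.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(block_size = 10, min_diameter, max_diameter) {
  block_size <- as.integer(round(block_size))
  min_diameter <- as.integer(round(min_diameter))
  max_diameter <- as.integer(round(max_diameter))
  if (block_size < 2L) stop("block_size must be >= 2", call. = FALSE)
  if (min_diameter < 1L) stop("min_diameter must be >= 1", call. = FALSE)
  if (min_diameter >= max_diameter) {
    stop("min_diameter must be < max_diameter", call. = FALSE)
  }
  structure(list(block_size = block_size, min_diameter = min_diameter,
                 max_diameter = max_diameter),
            class = "segmentation_params")
}

#' @export
print.well_record <- function(x, ...) {
  cat(sprintf(
    "well_record %s: source='%s' rotation=%g deg interval=%g min blocks=%d diam=[%d,%d] %s\n",
    x$well_id, x$source, x$rotation_deg, x$interval_min,
    x$seg_params$block_size, x$seg_params$min_diameter,
    x$seg_params$max_diameter,
    if (x$included) "included" else "EXCLUDED"))
  invisible(x)
}

#' Construct an image stack
#'
#' @param frames List of numeric matrices (row = image row), all of identical
#'   dimensions, in temporal order. At least two frames are required and all
#'   intensities must be non-negative.
#' @return An object of class `image_stack` with elements `frames`, `height`,
#'   `width`.
#' @export
image_stack <- function(frames) {
  if (length(frames) < 2L) {
    stop("time series required: an image stack needs at least 2 frames",
         call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames in a stack must have identical dimensions", call. = FALSE)
  }
  if (any(vapply(frames, function(f) any(f < 0), logical(1L)))) {
    stop("frame intensities must be non-negative", call. = FALSE)
  }
  structure(list(frames = frames, height = dims[1, 1], width = dims[2, 1]),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d frames of %d x %d px\n",
              length(x$frames), x$height, x$width))
  invisible(x)
}

# Read one TIFF as a non-negative numeric matrix on its stored integer scale.
# RGB/multi-channel frames are reduced to grayscale by the channel mean.
read_tiff_gray <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) {
                    stop("I/O error reading TIFF '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  storage.mode(img) <- "double"
  img
}

#' Load a well's TIFF image series
#'
#' Frames are read in lexicographic filename order, which is the temporal
#' order by the input convention (filenames encode acquisition order).
#' The source may be a plain folder of `.tif` files or a `.zip` archive
#' containing such a folder; archives are extracted to a temporary directory.
#'
#' @param record A [well_record()].
#' @param root Directory against which `record$source` is resolved.
#' @return An [image_stack()].
#' @export
load_stack <- function(record, root = ".") {
  src <- file.path(root, record$source)
  dir_path <- src
  if (!dir.exists(src)) {
    zip_candidates <- c(src, paste0(src, ".zip"))
    zip_path <- zip_candidates[file.exists(zip_candidates) & !dir.exists(zip_candidates)][1L]
    if (is.na(zip_path)) {
      stop("I/O error: well source not found: ", src, call. = FALSE)
    }
    exdir <- file.path(tempfile("well_"), record$well_id)
    utils::unzip(zip_path, exdir = exdir)
    # images may sit at the archive root or inside a single folder
    tifs <- list.files(exdir, pattern = "\\.tiff?$", ignore.case = TRUE,
                       recursive = TRUE, full.names = TRUE)
    if (length(tifs) == 0L) {
      stop("validation error: zip archive '", zip_path, "' holds no TIFF files",
           call. = FALSE)
    }
    dir_path <- unique(dirname(tifs))
    if (length(dir_path) > 1L) {
      stop("validation error: zip archive '", zip_path,
           "' holds TIFFs in more than one folder", call. = FALSE)
    }
  }
  files <- list.files(dir_path, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- files[order(basename(files), method = "radix")]
  if (length(files) < 2L) {
    stop("validation error: time series required (found ", length(files),
         " TIFF frame(s) in ", dir_path, ")", call. = FALSE)
  }
  frames <- lapply(files, read_tiff_gray)
  dims <- vapply(frames, dim, integer(2L))
  if (any(dims != dims[, 1])) {
    stop("validation error: frames of mismatched shape in ", dir_path,
         call. = FALSE)
  }
  image_stack(frames)
}

#' Mark wells as excluded from analysis
#'
#' Mirrors re-indexing a plate after technical failures: the records stay in
#' the index (and in run metadata) but are skipped by the pipeline.
#'
#' @param records List of [well_record()]s.
#' @param excluded Character vector of well ids to exclude.
#' @return A new list of records, same order and length, with `included` set
#'   to `FALSE` for the excluded wells.
#' @export
filter_index <- function(records, excluded = character()) {
  excluded <- as.character(excluded)
  ids <- vapply(records, function(r) r$well_id, character(1L))
  unknown <- setdiff(excluded, ids)
  if (length(unknown) > 0L) {
    stop("validation error: unknown well_id in exclusion set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lapply(records, function(r) {
    if (r$well_id %in% excluded) r$included <- FALSE
    r
  })
}

#' Serialize well records back to the index dialect
#'
#' Only included records are written, so parse -> exclude -> serialize is the
#' programmatic equivalent of making a new index file.
#'
#' @param records List of [well_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(records, path) {
  header <- paste(c("well", "folder", "rotation_deg", "interval_min",
                    "block_size", "min_diameter", "max_diameter"),
                  collapse = "\t")
  rows <- vapply(records[vapply(records, function(r) r$included, logical(1L))],
                 function(r) {
                   paste(c(r$well_id, r$source,
                           format(r$rotation_deg), format(r$interval_min),
                           r$seg_params$block_size, r$seg_params$min_diameter,
                           r$seg_params$max_diameter), collapse = "\t")
                 }, character(1L))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}
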