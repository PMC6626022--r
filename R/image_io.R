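#' @importFrom tiff readTIFF writeTIFF
#' @importFrom utils write.csv read.csv
NULL

new_mm_frame <- function(primary, fluorescence = list(), area_id = NA_character_,
                         timestamp = as.POSIXct(NA), path = NA_character_) {
  stopifnot(is.matrix(primary))
  for (f in fluorescence) {
    if (!identical(dim(f), dim(primary))) {
      stop("fluorescence plane dimensions differ from the primary plane")
    }
  }
  structure(list(primary = primary, fluorescence = fluorescence,
                 area_id = area_id, timestamp = timestamp, path = path),
            class = "mm_frame")
}

#' @export
print.mm_frame <- function(x, ...) {
  cat(sprintf("mm_frame %dx%d px, %d fluorescence plane(s), area %s, %s\n",
              nrow(x$primary), ncol(x$primary), length(x$fluorescence),
              x$area_id, format(x$timestamp)))
  invisible(x)
}

#' Parse a protocol filename into area id and timestamp
#'
#' Batch folders follow the naming protocol `<area>_YYMMDD_HHMMSS.tiff`, e.g.
#' `Area01_171016_123301.tiff` for area 1 imaged at 12:33:01 on 16 October
#' 2017. The area id is everything before the trailing `_YYMMDD_HHMMSS`
#' (it may itself contain underscores); two-digit years map to 2000--2099.
#'
#' @param name File name (with or without directory and extension).
#' @return A list with `area_id` (character) and `timestamp` (POSIXct, UTC).
#' @examples
#' mm_parse_filename("Area01_171016_123301.tiff")
#' @export
mm_parse_filename <- function(name) {
  base <- sub("\\.[Tt][Ii][Ff][Ff]?$", "", basename(name))
  m <- regmatches(base, regexec("^(.+)_([0-9]{6})_([0-9]{6})$", base))[[1]]
  if (length(m) != 4) {
    stop("filename does not follow the <area>_YYMMDD_HHMMSS protocol: ",
         basename(name))
  }
  d <- m[3]; tm <- m[4]
  yy <- as.integer(substr(d, 1, 2)); mo <- as.integer(substr(d, 3, 4))
  dd <- as.integer(substr(d, 5, 6))
  hh <- as.integer(substr(tm, 1, 2)); mi <- as.integer(substr(tm, 3, 4))
  ss <- as.integer(substr(tm, 5, 6))
  if (mo < 1 || mo > 12 || dd < 1 || dd > 31 || hh > 23 || mi > 59 || ss > 59) {
    stop("malformed date/time fields in filename: ", basename(name))
  }
  ts <- ISOdatetime(2000 + yy, mo, dd, hh, mi, ss, tz = "UTC")
  if (is.na(ts)) stop("invalid calendar date in filename: ", basename(name))
  list(area_id = m[2], timestamp = ts)
}

#' Load one time point from a TIFF file
#'
#' Reads a single- or multi-page grayscale TIFF. The first page is the
#' detection (brightfield / phase contrast) plane; the remaining `n_fluo`
#' pages are fluorescence planes in acquisition order. Intensities are
#' returned on `[0, 1]` for integer TIFFs (the `tiff` package convention).
#'
#' @param path Path to a TIFF file named by the protocol (see
#'   [mm_parse_filename()]); non-protocol names are accepted for single-image
#'   runs (area id and timestamp left `NA`).
#' @param n_fluo Expected number of fluorescence planes.
#' @return An `mm_frame`: list with `primary` (matrix), `fluorescence` (list
#'   of matrices), `area_id`, `timestamp`, `path`.
#' @export
mm_load_frame <- function(path, n_fluo = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  planes <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1] # collapse grayscale-as-RGB
    p
  })
  if (length(planes) != 1 + n_fluo) {
    stop(sprintf("%s: expected %d plane(s) (1 detection + %d fluorescence), found %d",
                 basename(path), 1 + n_fluo, n_fluo, length(planes)))
  }
  meta <- tryCatch(mm_parse_filename(path),
                   error = function(e) list(area_id = NA_character_,
                                            timestamp = as.POSIXct(NA)))
  new_mm_frame(planes[[1]], planes[-1], area_id = meta$area_id,
               timestamp = meta$timestamp, path = path)
}

#' Index a batch folder by area and time
#'
#' Scans a folder for TIFF files following the naming protocol and groups
#' them by area, ordered chronologically. Every matching file is indexed
#' exactly once; the result does not depend on filesystem enumeration order.
#'
#' @param folder Directory to scan.
#' @return A list of class `mm_batch_index`: one element per area id, each a
#'   data frame with columns `path`, `timestamp`, sorted by timestamp.
#' @export
mm_index_batch <- function(folder) {
  files <- list.files(folder, pattern = "\\.[Tt][Ii][Ff][Ff]?$",
                      full.names = TRUE)
  parsed <- lapply(files, function(f) {
    tryCatch(c(mm_parse_filename(f), list(path = f)),
             error = function(e) NULL)
  })
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  if (!length(parsed)) {
    return(structure(list(), class = "mm_batch_index"))
  }
  df <- data.frame(
    area_id = vapply(parsed, `[[`, character(1), "area_id"),
    path = vapply(parsed, `[[`, character(1), "path"),
    timestamp = as.POSIXct(vapply(parsed, function(p)
      as.numeric(p$timestamp), numeric(1)), origin = "1970-01-01", tz = "UTC")
  )
  out <- lapply(split(df, df$area_id), function(a) {
    a <- a[order(a$timestamp, a$path), c("path", "timestamp")]
    if (anyDuplicated(a$timestamp)) {
      warning("duplicate timestamps within area; ordering by path as tie-break")
    }
    rownames(a) <- NULL
    a
  })
  structure(out, class = "mm_batch_index")
}

#' @export
print.mm_batch_index <- function(x, ...) {
  cat("mm_batch_index:", length(x), "area(s)\n")
  for (a in names(x)) cat(sprintf("  %s: %d frame(s)\n", a, nrow(x[[a]])))
  invisible(x)
}

measurement_columns <- function(n_fluo) {
  c("area_id", "timestamp", "frame_index", "channel_id", "bacterium_id",
    "parent_id", "event", "length_px", "width_px", "area_px",
    as.vector(rbind(sprintf("fluo%d_mean", seq_len(n_fluo)),
                    sprintf("fluo%d_background", seq_len(n_fluo)))))
}

#' Write per-bacterium measurements to CSV
#'
#' One row per bacterium per time point with the fixed schema: `area_id`,
#' `timestamp`, `frame_index`, `channel_id`, `bacterium_id`, `parent_id`,
#' `event`, `length_px`, `width_px`, `area_px`, then one
#' `(fluo<k>_mean, fluo<k>_background)` pair per fluorescence channel.
#'
#' @param records Data frame of measurements (see [mm_measurements()]); an
#'   empty data frame yields a header-only CSV.
#' @param path Output file path.
#' @param n_fluo Number of fluorescence channels in the schema (defaults to
#'   the number present in `records`).
#' @return Invisibly, the path written.
#' @export
mm_write_measurements <- function(records, path, n_fluo = NULL) {
  if (is.null(n_fluo)) {
    n_fluo <- sum(grepl("^fluo[0-9]+_mean$", names(records)))
  }
  cols <- measurement_columns(n_fluo)
  if (nrow(records) == 0) {
    records <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    missing <- setdiff(cols, names(records))
    for (mcol in missing) records[[mcol]] <- NA
    records <- records[, cols]
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a measurement CSV written by [mm_write_measurements()]
#' @param path CSV path.
#' @return Data frame with the measurement schema.
#' @export
mm_read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("timestamp" %in% names(df)) {
    df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  }
  df
}

#' Write a synthetic series to protocol-named TIFFs
#'
#' Writes each frame (primary plane plus fluorescence planes as a multi-page
#' TIFF) under the naming protocol, plus per-frame ground-truth label TIFFs
#' and a lineage JSON, so a folder generated here can be re-analysed through
#' the batch interface.
#'
#' @param series An `mm_fixture_series` from [mm_generate_series()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
mm_write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmax <- max(1, series$spec$fluo_background +
                series$spec$fluo_cell_mean + 5 * series$spec$fluo_cell_sd)
  for (t in seq_along(series$frames)) {
    fr <- series$frames[[t]]
    name <- sprintf("%s_%s.tiff", fr$area_id,
                    format(fr$timestamp, "%y%m%d_%H%M%S"))
    planes <- c(list(fr$primary),
                lapply(fr$fluorescence, function(f) clamp(f / fmax, 0, 1)))
    tiff::writeTIFF(planes, file.path(dir, name), bits.per.sample = 16L)
    truth_name <- sprintf("truth_%03d.tiff", t)
    lab <- series$truth$bacteria_labels[[t]]
    tiff::writeTIFF(lab / max(1, max(lab)), file.path(dir, truth_name),
                    bits.per.sample = 16L)
  }
  jsonlite::write_json(series$truth$lineage,
                       file.path(dir, "lineage.json"), digits = NA)
  invisible(dir)
}
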