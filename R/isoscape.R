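#' Construct a gridded sea-surface delta-18O isoscape
#'
#' A regular latitude x longitude grid of seawater delta-18O (per mil VSMOW)
#' with `NA` marking land or no-data cells. Latitudes are normalised to
#' ascending order and longitudes wrapped to [-180, 180); cell-center
#' convention throughout.
#'
#' @param lat Cell-center latitudes, degrees (any order; stored ascending).
#' @param lon Cell-center longitudes, degrees.
#' @param values Numeric matrix, `length(lat)` rows x `length(lon)` columns.
#' @return An object of class `isoscape_grid`: list with `lat`, `lon`,
#'   `values`.
#' @export
isoscape_grid <- function(lat, lon, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon)) {
    stop("values must be a length(lat) x length(lon) matrix", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitudes must lie within [-90, 90]", call. = FALSE)
  }
  lon <- ((lon + 180) %% 360) - 180
  if (is.unsorted(lat)) {
    ord <- order(lat)
    lat <- lat[ord]
    values <- values[ord, , drop = FALSE]
  }
  if (all(is.na(values))) stop("empty grid: all cells missing", call. = FALSE)
  dimnames(values) <- NULL
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 values = values),
            class = "isoscape_grid")
}

#' @export
print.isoscape_grid <- function(x, ...) {
  cat(sprintf("isoscape grid: %d lat x %d lon cells, %d missing; d18O range [%.2f, %.2f]\n",
              length(x$lat), length(x$lon), sum(is.na(x$values)),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Read an isoscape from a CSV grid
#'
#' Grid dialect: the first row holds longitudes (top-left cell blank or a
#' label), the first column latitudes, the body the delta-18O values; empty
#' cells are missing. Latitude order in the file is irrelevant — the grid is
#' normalised ascending on read.
#'
#' @param path Path to the CSV grid.
#' @return An [isoscape_grid()].
#' @export
read_isoscape <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (nrow(raw) < 2L || ncol(raw) < 2L) {
    stop("format error: CSV grid needs a longitude header row and a latitude column",
         call. = FALSE)
  }
  lon <- suppressWarnings(as.numeric(raw[1L, -1L]))
  lat <- suppressWarnings(as.numeric(raw[-1L, 1L]))
  if (any(is.na(lon))) stop("format error: unparsable longitude header", call. = FALSE)
  if (any(is.na(lat))) stop("format error: unparsable latitude column", call. = FALSE)
  body <- as.matrix(raw[-1L, -1L, drop = FALSE])
  values <- matrix(suppressWarnings(as.numeric(body)),
                   nrow = length(lat), ncol = length(lon))
  isoscape_grid(lat, lon, values)
}

#' Write an isoscape to the CSV grid dialect
#'
#' @param grid An [isoscape_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_isoscape()] for the dialect; a write/read cycle is the
#'   identity.
#' @export
write_isoscape <- function(grid, path) {
  header <- c("lat_lon", format(grid$lon, trim = TRUE, digits = 15))
  rows <- cbind(format(grid$lat, trim = TRUE, digits = 15),
                ifelse(is.na(grid$values), "",
                       format(grid$values, trim = TRUE, digits = 15)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(rows, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Cells encompassed by a delta-18O interval
#'
#' The geographic-assignment primitive: a cell is assigned iff it is
#' non-missing and its isoscape value lies inside the closed interval
#' `[lo, hi]` (boundary cells count). Widening the interval can only add
#' cells. An `empty` flag records the case where the interval lies wholly
#' outside the isoscape's range of values.
#'
#' @param grid An [isoscape_grid()].
#' @param interval Numeric length-2 vector `c(lo, hi)`, per mil.
#' @param specimen_id Optional id carried on the mask.
#' @return An object of class `assignment_mask`: list with `specimen_id`,
#'   `interval`, `mask` (logical lat x lon matrix), `n_cells`, `empty`.
#' @export
assign_interval <- function(grid, interval, specimen_id = NA_character_) {
  if (length(interval) != 2L || any(is.na(interval))) {
    stop("interval must be c(lo, hi) with no missing values", call. = FALSE)
  }
  if (interval[1L] > interval[2L]) {
    stop("interval error: lo > hi", call. = FALSE)
  }
  mask <- !is.na(grid$values) &
    grid$values >= interval[1L] & grid$values <= interval[2L]
  n <- sum(mask)
  structure(list(specimen_id = specimen_id,
                 interval = as.numeric(interval),
                 mask = mask, n_cells = n, empty = n == 0L),
            class = "assignment_mask")
}

#' Assign a set of specimens to isoscape cells
#'
#' One [assign_interval()] mask per marine estimate, using each specimen's
#' confidence interval `(ci_lo, ci_hi)`; input order preserved. Only the
#' estimate-side variance enters the interval — isoscape-side prediction
#' variance is deliberately not modelled.
#'
#' @param estimates Data frame from [estimate_marine()].
#' @param grid An [isoscape_grid()].
#' @return List of `assignment_mask` objects.
#' @export
assign_specimens <- function(estimates, grid) {
  lapply(seq_len(nrow(estimates)), function(i) {
    assign_interval(grid, c(estimates$ci_lo[i], estimates$ci_hi[i]),
                    specimen_id = estimates$specimen_id[i])
  })
}

#' Summarise an assignment mask
#'
#' @param mask An `assignment_mask`.
#' @param grid The [isoscape_grid()] it was computed on.
#' @return One-row data frame: `specimen_id`, `n_cells`, `fraction` (of
#'   non-missing cells), `empty`, `lat_min`, `lat_max`, `lat_mean` (`NA`
#'   for an empty mask).
#' @export
mask_summary <- function(mask, grid) {
  if (!all(dim(mask$mask) == dim(grid$values))) {
    stop("mask and grid shapes disagree", call. = FALSE)
  }
  n_valid <- sum(!is.na(grid$values))
  lat_cells <- matrix(grid$lat, nrow = length(grid$lat), ncol = length(grid$lon))
  lats <- lat_cells[mask$mask]
  data.frame(specimen_id = mask$specimen_id,
             n_cells = mask$n_cells,
             fraction = mask$n_cells / n_valid,
             empty = mask$empty,
             lat_min = if (mask$empty) NA_real_ else min(lats),
             lat_max = if (mask$empty) NA_real_ else max(lats),
             lat_mean = if (mask$empty) NA_real_ else mean(lats),
             stringsAsFactors = FALSE)
}

#' Summary table for a list of masks
#'
#' @param masks List of `assignment_mask` objects.
#' @param grid The [isoscape_grid()].
#' @return Data frame, one row per mask (see [mask_summary()]).
#' @export
assignment_summary <- function(masks, grid) {
  out <- do.call(rbind, lapply(masks, mask_summary, grid = grid))
  rownames(out) <- NULL
  out
}

#' Write an assignment mask as CSV
#'
#' Same grid dialect as [write_isoscape()], with cell values 1 (assigned),
#' 0 (not assigned) and empty (missing in the isoscape).
#'
#' @param mask An `assignment_mask`.
#' @param grid The [isoscape_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, grid, path) {
  vals <- matrix(NA_real_, nrow = length(grid$lat), ncol = length(grid$lon))
  vals[!is.na(grid$values)] <- 0
  vals[mask$mask] <- 1
  write_isoscape(isoscape_grid(grid$lat, grid$lon, vals), path)
}
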