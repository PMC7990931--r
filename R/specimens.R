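#' Read a specimen table
#'
#' Reads a CSV of whale specimen records. The file must carry a header naming
#' at least `specimen_id`, `region`, `tissue`, `year_of_death` and `d18O_p`;
#' `age_years`, `d13C_sc` and `stranding_group` are optional. Empty cells
#' become `NA` (never zero) and row order is preserved.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A data frame with one row per specimen, columns
#'   `specimen_id`, `region`, `tissue`, `year_of_death`, `age_years`,
#'   `d18O_p`, `d13C_sc`, `stranding_group`. Isotope values are per mil
#'   (delta-18O of phosphate vs VSMOW; delta-13C of structural carbonate vs
#'   VPDB).
#' @seealso [validate_specimens()], [orca_specimens()]
#' @export
read_specimens <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  mandatory <- c("specimen_id", "region", "tissue", "year_of_death", "d18O_p")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0L) {
    stop("specimen table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  optional <- c("age_years", "d13C_sc", "stranding_group")
  for (col in setdiff(optional, names(raw))) {
    raw[[col]] <- rep(NA_character_, nrow(raw))
  }
  num_cols <- c("year_of_death", "age_years", "d18O_p", "d13C_sc")
  for (col in num_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(parsed))
    if (length(bad) > 0L) {
      stop(sprintf("unparsable number in column '%s' at data row %d: '%s'",
                   col, bad[1L], raw[[col]][bad[1L]]), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  out <- raw[, c("specimen_id", "region", "tissue", "year_of_death",
                 "age_years", "d18O_p", "d13C_sc", "stranding_group")]
  rownames(out) <- NULL
  out
}

#' Write a specimen table
#'
#' Inverse of [read_specimens()]: writes the standard CSV dialect with empty
#' strings for missing values, so a read/write cycle is the identity.
#'
#' @param records Specimen data frame as returned by [read_specimens()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-GLG isotope profiles
#'
#' Growth layer groups (GLGs) are annual dentine increments; a profile is the
#' yearly isotope time series of one tooth, stored long-format and keyed by
#' `specimen_id` with `glg_index` starting at 1.
#'
#' @param path Path to a CSV with columns
#'   `specimen_id,glg_index,d18O_sc,d13C_sc`.
#' @return A data frame with those columns; `glg_index` must be strictly
#'   increasing within each specimen.
#' @export
read_glg_profiles <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  mandatory <- c("specimen_id", "glg_index")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0L) {
    stop("GLG profile table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(c("d18O_sc", "d13C_sc"), names(raw))) {
    raw[[col]] <- rep(NA_character_, nrow(raw))
  }
  for (col in c("glg_index", "d18O_sc", "d13C_sc")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(parsed))
    if (length(bad) > 0L) {
      stop(sprintf("unparsable number in column '%s' at data row %d",
                   col, bad[1L]), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  out <- raw[, c("specimen_id", "glg_index", "d18O_sc", "d13C_sc")]
  for (id in unique(out$specimen_id)) {
    idx <- out$glg_index[out$specimen_id == id]
    if (length(idx) < 1L || any(diff(idx) <= 0)) {
      stop("glg_index must be strictly increasing within specimen ", id,
           call. = FALSE)
    }
  }
  rownames(out) <- NULL
  out
}

#' Validate specimen records
#'
#' Report-only sanity screen: flags phosphate delta-18O outside the
#' physically plausible window [0, 40] per mil, ages of 120 years or more,
#' and years of death before 1800. Missing age or delta-13C is allowed
#' (bone specimens have no GLG age reading). Never mutates its input.
#'
#' @param records Specimen data frame.
#' @return A data frame of violations with columns
#'   `specimen_id`, `row`, `field`, `message`; zero rows when clean.
#' @export
validate_specimens <- function(records) {
  report <- list()
  flag <- function(i, field, message) {
    report[[length(report) + 1L]] <<- data.frame(
      specimen_id = records$specimen_id[i], row = i,
      field = field, message = message, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    x <- records$d18O_p[i]
    if (is.na(x)) {
      flag(i, "d18O_p", "missing d18O_p")
    } else if (x < 0 || x > 40) {
      flag(i, "d18O_p", sprintf("d18O_p = %g outside sanity window [0, 40]", x))
    }
    age <- records$age_years[i]
    if (!is.na(age) && (age < 0 || age >= 120)) {
      flag(i, "age_years", sprintf("implausible age %g", age))
    }
    yr <- records$year_of_death[i]
    if (is.na(yr)) {
      flag(i, "year_of_death", "missing year of death")
    } else if (yr < 1800) {
      flag(i, "year_of_death", sprintf("year of death %g before 1800", yr))
    }
  }
  if (length(report) == 0L) {
    return(data.frame(specimen_id = character(), row = integer(),
                      field = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, report)
  rownames(out) <- NULL
  out
}

#' Packaged killer whale specimen fixture
#'
#' The 22 stranded killer whales analysed in the study: 10 eastern Canadian
#' Arctic (ECA) and 7 northwest Atlantic (NWA) teeth, 2 Greenland and 3
#' Denmark mandibular bones, with year of death, GLG age (where read),
#' whole-tooth/bone phosphate delta-18O and raw structural-carbonate
#' delta-13C. One ECA tooth (ECA-CS-1977-3) has no age reading.
#'
#' @return Specimen data frame, see [read_specimens()].
#' @export
orca_specimens <- function() {
  read_specimens(system.file("extdata", "killer_whale_specimens.csv",
                             package = "orcascape", mustWork = TRUE))
}

#' Published per-specimen results for cross-checking
#'
#' The published per-specimen marine delta-18O estimates (point value and
#' propagated SE) and Suess-adjusted delta-13C. Two NWA rows are flagged
#' `suess_swapped`: their printed adjusted delta-13C cells are interchanged
#' relative to the stated correction formula (each matches the formula
#' applied to the other's raw value). Bone rows are flagged `suess_excluded`:
#' with no age reading their printed adjusted values cannot be reconstructed
#' from the stated formula.
#'
#' @return Data frame with columns `specimen_id`, `m_hat_printed`,
#'   `se_printed`, `d13C_sc_suess_printed`, `suess_swapped`, `suess_excluded`.
#' @export
orca_printed_values <- function() {
  path <- system.file("extdata", "killer_whale_table_printed.csv",
                      package = "orcascape", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$suess_swapped <- as.logical(out$suess_swapped)
  out$suess_excluded <- as.logical(out$suess_excluded)
  out
}
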