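#' Rank Argos location-quality classes
#'
#' Argos satellite fixes carry a quality class; positional error grows through
#' the ordering `3 < 2 < 1 < 0 < A < B < Z`. The deployment fix (`"D"`) is a
#' known position and ranks best of all.
#'
#' @param cls Character vector of Argos class codes; allowed values are
#'   `"D"`, `"3"`, `"2"`, `"1"`, `"0"`, `"A"`, `"B"`, `"Z"`.
#' @return Integer vector of ranks, 0 (best, deployment) through 7 (worst).
#' @examples
#' argos_rank(c("3", "B", "D"))
#' @export
argos_rank <- function(cls) {
  order_codes <- c("D", "3", "2", "1", "0", "A", "B", "Z")
  cls <- as.character(cls)
  idx <- match(cls, order_codes)
  if (anyNA(idx)) {
    bad <- unique(cls[is.na(idx)])
    abort(paste0("Unknown Argos class code(s): ", paste(bad, collapse = ", ")))
  }
  idx - 1L
}

#' Keep the single best-quality location per tag per day
#'
#' Telemetry tags often report several fixes on one day; only the highest
#' quality fix per UTC calendar day is retained, so day gaps in the track are
#' preserved and no interpolation takes place. Ties in quality are broken by
#' the earliest timestamp.
#'
#' @param locations Data frame with columns `tag_id`, `timestamp` (POSIXct,
#'   treated as UTC), `lon`, `lat`, `argos_class`.
#' @return A tibble with at most one row per `(tag_id, day)`, ordered by tag
#'   and time.
#' @export
filter_daily_best <- function(locations) {
  locations <- as_tibble(locations)
  req <- c("tag_id", "timestamp", "lon", "lat", "argos_class")
  missing_cols <- setdiff(req, names(locations))
  if (length(missing_cols) > 0) {
    abort(paste0("filter_daily_best() needs column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(locations) == 0) return(locations)
  locations %>%
    mutate(
      .day = as.Date(.data$timestamp, tz = "UTC"),
      .rank = argos_rank(.data$argos_class)
    ) %>%
    group_by(.data$tag_id, .data$.day) %>%
    arrange(.data$.rank, .data$timestamp, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    arrange(.data$tag_id, .data$timestamp) %>%
    select(-".day", -".rank")
}

#' Binary east/west movement response
#'
#' Codes each longitude against a fixed meridian: 1 when the position lies
#' strictly west of the boundary, 0 when east of (or exactly on) it. This is
#' the binary response modelled throughout the package.
#'
#' @param longitude Numeric vector, decimal degrees (west negative).
#' @param boundary Boundary meridian in decimal degrees (default -125, i.e.
#'   125 degrees West).
#' @return Integer vector of 0/1.
#' @examples
#' derive_response(c(-120, -130, -125))
#' @export
derive_response <- function(longitude, boundary = -125) {
  if (!is.numeric(longitude) || any(!is.finite(longitude))) {
    abort("`longitude` must be finite numeric.")
  }
  as.integer(longitude < boundary)
}

#' Z-score standardization
#'
#' Centres and scales a covariate to mean 0, sd 1 so that coefficients across
#' covariates live on comparable scales, and returns the standardization
#' parameters so the same transform can be applied to new data.
#'
#' @param x Numeric vector with at least 2 non-identical values.
#' @param name Optional variable name recorded in the parameter table.
#' @return A list with `values` (standardized vector) and `params`
#'   (a one-row tibble: `variable`, `mean`, `sd`).
#' @examples
#' zscore(c(2, 4, 6))
#' @export
zscore <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 2) abort("zscore() needs at least 2 values.")
  m <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s <= 0) abort("zscore(): zero or undefined standard deviation.")
  list(
    values = (x - m) / s,
    params = tibble(variable = as.character(name), mean = m, sd = s)
  )
}

#' Season indicator encoding
#'
#' One-hot Northern-Hemisphere meteorological seasons: Spring = Mar-May,
#' Summer = Jun-Aug, Fall = Sep-Nov, Winter = Dec-Feb. Exactly one indicator
#' is 1 per date.
#'
#' @param timestamp Date or POSIXct vector.
#' @return Tibble with integer columns `Spring`, `Summer`, `Fall`, `Winter`.
#' @export
encode_season <- function(timestamp) {
  mo <- as.integer(format(as.Date(timestamp, tz = "UTC"), "%m"))
  tibble(
    Spring = as.integer(mo %in% 3:5),
    Summer = as.integer(mo %in% 6:8),
    Fall   = as.integer(mo %in% 9:11),
    Winter = as.integer(mo %in% c(12L, 1L, 2L))
  )
}

#' Track boundary index for grouped data
#'
#' The hierarchical model addresses each individual's rows by a cumulative
#' boundary vector: entry j is the 1-based starting row of group j, with a
#' final sentinel equal to the total row count plus one. Rows must therefore
#' be contiguous by group.
#'
#' @param data Data frame ordered so that each group's rows are contiguous.
#' @param group Name of the group id column (default `"ptt"`).
#' @return A list with `boundaries` (integer, length N + 1), `n_groups`,
#'   `groups` (the ids in row order).
#' @examples
#' build_track_index(data.frame(ptt = c("A", "A", "A", "B", "B")))
#' @export
build_track_index <- function(data, group = "ptt") {
  g <- as.character(data[[group]])
  if (is.null(g)) abort(paste0("Column `", group, "` not found."))
  r <- rle(g)
  if (anyDuplicated(r$values)) {
    dup <- r$values[duplicated(r$values)][1]
    row_bad <- sum(r$lengths[seq_len(which(duplicated(r$values))[1] - 1)]) + 1
    abort(paste0("Rows are not contiguous by `", group, "`: id \"", dup,
                 "\" reappears at row ", row_bad,
                 ". Order the table by individual before indexing."))
  }
  list(
    boundaries = as.integer(cumsum(c(1L, r$lengths))),
    n_groups = length(r$values),
    groups = r$values
  )
}

#' Extract a gridded covariate over a positional-error box
#'
#' Positional uncertainty of a satellite fix is matched to the resolution of
#' an environmental field by averaging every grid cell intersecting the
#' error box centred on the fix. Error half-widths are given in metres and
#' converted to degrees at the fix latitude (111,320 m per degree latitude;
#' scaled by cos(latitude) for longitude).
#'
#' @param grid Numeric matrix indexed `[lon, lat]`.
#' @param lon_axis,lat_axis Monotone numeric vectors of cell-centre
#'   coordinates matching `dim(grid)`.
#' @param lon,lat Fix coordinates (decimal degrees); vectors of equal length.
#' @param lon_err,lat_err Error half-widths in metres (scalar or vector).
#' @return Numeric vector of box means; `NA` where the fix lies outside the
#'   grid (with a warning) or every intersecting cell is missing.
#' @export
extract_grid_covariate <- function(grid, lon_axis, lat_axis, lon, lat,
                                   lon_err = 0, lat_err = 0) {
  stopifnot(is.matrix(grid), length(lon_axis) == nrow(grid),
            length(lat_axis) == ncol(grid))
  if (any(lon_err < 0) || any(lat_err < 0)) abort("Error radii must be >= 0.")
  n <- length(lon)
  lon_err <- rep_len(lon_err, n)
  lat_err <- rep_len(lat_err, n)
  m_per_deg <- 111320
  out <- rep(NA_real_, n)
  outside <- logical(n)
  half_dlon <- if (length(lon_axis) > 1) median(abs(diff(lon_axis))) / 2 else Inf
  half_dlat <- if (length(lat_axis) > 1) median(abs(diff(lat_axis))) / 2 else Inf
  for (i in seq_len(n)) {
    if (lon[i] < min(lon_axis) - half_dlon || lon[i] > max(lon_axis) + half_dlon ||
        lat[i] < min(lat_axis) - half_dlat || lat[i] > max(lat_axis) + half_dlat) {
      outside[i] <- TRUE
      next
    }
    dlat <- lat_err[i] / m_per_deg
    dlon <- lon_err[i] / (m_per_deg * max(cos(lat[i] * pi / 180), 1e-6))
    ii <- which(abs(lon_axis - lon[i]) <= dlon + half_dlon)
    jj <- which(abs(lat_axis - lat[i]) <= dlat + half_dlat)
    # error box smaller than one cell: fall back to the containing cell
    if (length(ii) == 0) ii <- which.min(abs(lon_axis - lon[i]))
    if (length(jj) == 0) jj <- which.min(abs(lat_axis - lat[i]))
    vals <- grid[ii, jj, drop = FALSE]
    if (any(!is.na(vals))) out[i] <- mean(vals, na.rm = TRUE)
  }
  if (any(outside)) {
    warn(paste0(sum(outside), " point(s) fall outside the grid extent; NA returned."))
  }
  out
}

#' Default per-class Argos error radii
#'
#' Mid-range positional error radii (metres) used when a class-specific value
#' is not supplied: latitude errors span roughly 326-1265 m and longitude
#' errors 742-3498 m over classes 3-1; classes 0/A/B/Z have no manufacturer
#' accuracy estimate and default to the worst documented radius.
#'
#' @return Tibble with columns `argos_class`, `lon_err`, `lat_err` (metres).
#' @export
argos_default_errors <- function() {
  tibble(
    argos_class = c("D", "3", "2", "1", "0", "A", "B", "Z"),
    lon_err = c(0, 742, 2120, 3498, 3498, 3498, 3498, 3498),
    lat_err = c(0, 326, 796, 1265, 1265, 1265, 1265, 1265)
  )
}

#' Build the standardized analysis table from raw locations
#'
#' Runs the preprocessing chain: daily best-quality filtering, east/west
#' response derivation, season encoding, z-scoring of per-individual length,
#' and sorting to contiguous tracks. Per-individual attributes (length, sex)
#' are supplied in a lookup table.
#'
#' @param locations Raw location data frame (`tag_id`, `timestamp`, `lon`,
#'   `lat`, `argos_class`).
#' @param individuals Data frame with one row per `tag_id`: columns `tag_id`,
#'   `length` (cm), `sex` (`"F"`/`"M"`).
#' @param index Optional data frame of a shared environmental index with
#'   columns `date`, `value`; joined by UTC day into `MEI_Index`.
#' @param boundary Boundary meridian for the response (default -125).
#' @return A list with `data` (the analysis tibble: `ptt`, `sex`, season
#'   indicators, `L`, `z`, optionally `MEI_Index`) and `standardization`
#'   (the length z-score parameters).
#' @export
build_analysis_table <- function(locations, individuals, index = NULL,
                                 boundary = -125) {
  filt <- filter_daily_best(locations)
  ind <- as_tibble(individuals)
  if (!all(c("tag_id", "length", "sex") %in% names(ind))) {
    abort("`individuals` needs columns tag_id, length, sex.")
  }
  zs <- zscore(ind$length[match(unique(filt$tag_id), ind$tag_id)], name = "L")
  len_std <- setNames(zs$values, unique(filt$tag_id))
  out <- filt %>%
    mutate(
      ptt = as.character(.data$tag_id),
      z = derive_response(.data$lon, boundary = boundary),
      sex = ind$sex[match(.data$tag_id, ind$tag_id)],
      L = unname(len_std[as.character(.data$tag_id)])
    )
  out <- dplyr::bind_cols(out, encode_season(out$timestamp))
  if (!is.null(index)) {
    idx <- as_tibble(index) %>%
      mutate(.day = as.Date(.data$date)) %>%
      select(".day", MEI_Index = "value")
    out <- out %>%
      mutate(.day = as.Date(.data$timestamp, tz = "UTC")) %>%
      left_join(idx, by = ".day") %>%
      select(-".day")
  }
  keep <- c("ptt", "sex", "Spring", "Summer", "Fall", "Winter", "L", "z",
            intersect("MEI_Index", names(out)))
  out <- out %>% arrange(.data$ptt, .data$timestamp) %>% select(all_of(keep))
  list(data = out, standardization = zs$params)
}

# Shared validator for analysis tables: one-hot seasons, binary response,
# contiguous groups, no missing values in modelled columns.
validate_analysis_table <- function(data, group = "ptt", response = "z") {
  data <- as_tibble(data)
  seasons <- c("Spring", "Summer", "Fall", "Winter")
  missing_cols <- setdiff(c(group, response, seasons), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Analysis table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  zc <- data[[response]]
  zc_num <- suppressWarnings(as.numeric(as.character(zc)))
  if (anyNA(zc_num) || !all(zc_num %in% c(0, 1))) {
    bad <- which(!zc_num %in% c(0, 1) | is.na(zc_num))[1]
    abort(paste0("Response `", response, "` must be 0/1; offending row ", bad,
                 " has value \"", as.character(zc[bad]), "\"."))
  }
  ssum <- rowSums(sapply(seasons, function(sn) as.numeric(as.character(data[[sn]]))))
  if (any(ssum != 1)) {
    abort(paste0("Season indicators must sum to 1 on every row; first bad row: ",
                 which(ssum != 1)[1], "."))
  }
  modelled <- intersect(c(group, response, seasons, "L", "sex", "MEI_Index"),
                        names(data))
  cc <- complete.cases(data[modelled])
  if (!all(cc)) {
    abort(paste0("Missing values in modelled columns at row ", which(!cc)[1], "."))
  }
  build_track_index(data, group = group)  # errors on non-contiguous groups
  invisible(data)
}
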