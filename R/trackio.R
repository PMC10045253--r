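# Reading Movebank-dialect GPS fix tables, trajectory kinematics, the
# five-filter quality cascade and bird-year splitting.

#' Default Movebank export column mapping
#'
#' Maps the pipeline's canonical column names to the column names of a
#' Movebank CSV export.
#'
#' @param bird_id,timestamp,lon,lat Column names in the input file.
#' @return Named list usable as the `dialect` argument of [read_fixes()].
#' @export
movebank_dialect <- function(bird_id = "individual-local-identifier",
                             timestamp = "timestamp",
                             lon = "location-long",
                             lat = "location-lat") {
  list(bird_id = bird_id, timestamp = timestamp, lon = lon, lat = lat)
}

#' Filter-cascade configuration
#'
#' Thresholds of the five-stage quality cascade: the Iberia/Morocco winter
#' bounding box, the September–March non-breeding season, the 4–61 minute
#' sampling-interval window, the 100 km/h speed ceiling and the minimum number
#' of fixes a bird-year must retain.
#'
#' @param lat_box,lon_box Winter bounding box (degrees).
#' @param season_months Months of the non-breeding season (1-12).
#' @param min_dt_min Fixes closer than this to the last kept fix are thinned.
#' @param max_dt_min Gaps of at least this many minutes start a new segment.
#' @param max_speed_kmh Fixes implying faster flight are deleted.
#' @param min_fixes_per_birdyear Bird-years with fewer fixes are removed.
#' @return A `filter_config` list.
#' @export
filter_config <- function(lat_box = c(30.0, 42.5),
                          lon_box = c(-10.0, 3.5),
                          season_months = c(9:12, 1:3),
                          min_dt_min = 4,
                          max_dt_min = 61,
                          max_speed_kmh = 100,
                          min_fixes_per_birdyear = 1000) {
  stopifnot(min_dt_min < max_dt_min, min_dt_min > 0, max_speed_kmh > 0,
            min_fixes_per_birdyear > 0)
  structure(list(lat_box = lat_box, lon_box = lon_box,
                 season_months = as.integer(season_months),
                 min_dt_min = min_dt_min, max_dt_min = max_dt_min,
                 max_speed_kmh = max_speed_kmh,
                 min_fixes_per_birdyear = min_fixes_per_birdyear),
            class = "filter_config")
}

#' Read GPS fixes from a Movebank-dialect CSV
#'
#' Rows are sorted by (bird, timestamp); duplicated (bird, timestamp) rows are
#' collapsed to the first occurrence. Timestamps are interpreted as UTC.
#'
#' @param path CSV file.
#' @param dialect Column-name mapping, see [movebank_dialect()].
#' @return Tibble with columns `bird_id`, `timestamp` (POSIXct, UTC), `lon`,
#'   `lat`, carrying a `read_report` attribute (rows read, duplicates dropped,
#'   birds).
#' @export
read_fixes <- function(path, dialect = movebank_dialect()) {
  if (!file.exists(path)) stop("fix file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(unlist(dialect), names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  raw_ts <- raw[[dialect$timestamp]]
  ts <- as.POSIXct(rep(NA_real_, length(raw_ts)), origin = "1970-01-01",
                   tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(ts) & !is.na(raw_ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(raw_ts[todo], fmt, tz = "UTC"), tz = "UTC")
  }
  bad_ts <- which(is.na(ts) & !is.na(raw[[dialect$timestamp]]))
  if (length(bad_ts))
    stop("unparseable timestamp at row(s): ",
         paste(utils::head(bad_ts, 5), collapse = ", "))
  fixes <- tibble::tibble(
    bird_id = as.character(raw[[dialect$bird_id]]),
    timestamp = ts,
    lon = as.numeric(raw[[dialect$lon]]),
    lat = as.numeric(raw[[dialect$lat]])
  )
  bad_lat <- which(is.na(fixes$lat) | abs(fixes$lat) > 90)
  if (length(bad_lat))
    stop("invalid latitude at row(s): ", paste(utils::head(bad_lat, 5), collapse = ", "))
  bad_lon <- which(is.na(fixes$lon) | abs(fixes$lon) > 180)
  if (length(bad_lon))
    stop("invalid longitude at row(s): ", paste(utils::head(bad_lon, 5), collapse = ", "))
  n_raw <- nrow(fixes)
  fixes <- fixes[order(fixes$bird_id, fixes$timestamp), ]
  dup <- duplicated(fixes[, c("bird_id", "timestamp")])
  fixes <- fixes[!dup, ]
  attr(fixes, "read_report") <- list(
    rows_read = n_raw, duplicates_dropped = sum(dup),
    fixes = nrow(fixes), birds = length(unique(fixes$bird_id))
  )
  fixes
}

#' Annotate per-bird trajectory kinematics
#'
#' Adds, for each fix, the time difference (`dt_min`, minutes), great-circle
#' distance (`dist_km`) and speed (`speed_kmh`) from the previous fix of the
#' same bird, plus a `segment_start` flag marking the first fix of each bird
#' and fixes following a transmission gap of at least `gap_flag_min` minutes.
#' Kinematics carried by a fix describe its *incoming* step.
#'
#' @param fixes Fix tibble, time-sorted within bird.
#' @param gap_flag_min Gap length (minutes) opening a new segment; `Inf`
#'   disables gap flagging.
#' @return The tibble with `dt_min`, `dist_km`, `speed_kmh`, `segment_start`.
#' @export
annotate_kinematics <- function(fixes, gap_flag_min = 61) {
  ord <- order(fixes$bird_id, fixes$timestamp)
  fixes <- fixes[ord, ]
  n <- nrow(fixes)
  if (n == 0) {
    fixes$dt_min <- numeric(0); fixes$dist_km <- numeric(0)
    fixes$speed_kmh <- numeric(0); fixes$segment_start <- logical(0)
    return(fixes)
  }
  same_bird <- c(FALSE, fixes$bird_id[-1] == fixes$bird_id[-n])
  dt <- c(NA_real_, as.numeric(difftime(fixes$timestamp[-1],
                                        fixes$timestamp[-n], units = "mins")))
  dt[!same_bird] <- NA_real_
  if (any(dt <= 0, na.rm = TRUE))
    stop("non-increasing timestamps within a bird after deduplication")
  dist <- c(NA_real_, haversine_km(fixes$lon[-n], fixes$lat[-n],
                                   fixes$lon[-1], fixes$lat[-1]))
  dist[!same_bird] <- NA_real_
  fixes$dt_min <- dt
  fixes$dist_km <- dist
  fixes$speed_kmh <- dist / (dt / 60)
  fixes$segment_start <- !same_bird | (!is.na(dt) & dt >= gap_flag_min)
  fixes
}

# Forward relinking speed sweep for one bird: drop a fix if its implied speed
# from the last kept fix exceeds the ceiling. Returns a logical keep vector.
.speed_sweep <- function(ts_min, lon, lat, max_speed) {
  n <- length(ts_min)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  for (i in seq_len(n)[-1]) {
    v <- haversine_km(lon[last], lat[last], lon[i], lat[i]) /
      ((ts_min[i] - ts_min[last]) / 60)
    if (v <= max_speed) {
      keep[i] <- TRUE
      last <- i
    }
  }
  keep
}

# Greedy forward thinning: keep a fix only if it is more than `min_dt` minutes
# after the last kept fix. Returns a logical keep vector for one bird.
.thin_bird <- function(ts_min, min_dt) {
  n <- length(ts_min)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- ts_min[1]
  for (i in seq_len(n)[-1]) {
    if (ts_min[i] - last > min_dt) {
      keep[i] <- TRUE
      last <- ts_min[i]
    }
  }
  keep
}

#' Apply the five-filter quality cascade
#'
#' Stages, in order: (1) drop birds whose December–February median position
#' lies outside the winter bounding box; (2) keep only September–March fixes;
#' (3) thin to a sampling interval of more than `min_dt_min` minutes (fixes
#' arriving after a gap of `max_dt_min` minutes or more are kept but flagged
#' as segment starts); (4) delete fixes implying speeds above
#' `max_speed_kmh`, re-annotating and repeating until no deletion (at most 10
#' passes); (5) drop bird-years with fewer than `min_fixes_per_birdyear`
#' fixes. Kinematics are recomputed after stages 3 and 4.
#'
#' @param fixes Fix tibble from [read_fixes()] (kinematics not required; they
#'   are computed internally).
#' @param config A [filter_config()].
#' @return Filtered, annotated fix tibble with a `filter_report` attribute:
#'   `$stages` (stage, n_in, n_dropped, n_out) and `$by_bird` (per-bird drop
#'   counts per stage).
#' @export
filter_cascade <- function(fixes, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  stages <- list()
  by_bird <- list()
  note_stage <- function(stage, before, after) {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = stage, n_in = nrow(before), n_dropped = nrow(before) - nrow(after),
      n_out = nrow(after))
    tb <- table(before$bird_id); ta <- table(after$bird_id)
    birds <- names(tb)
    dropped <- as.integer(tb) - as.integer(ifelse(is.na(ta[birds]), 0, ta[birds]))
    by_bird[[length(by_bird) + 1]] <<- tibble::tibble(
      stage = stage, bird_id = birds, n_dropped = dropped)
  }

  # stage 1: winter residency box (Dec-Feb median position per bird)
  before <- fixes
  mo <- as.integer(format(fixes$timestamp, "%m"))
  winter <- fixes[mo %in% c(12L, 1L, 2L), ]
  med <- dplyr::summarise(dplyr::group_by(winter, .data$bird_id),
                          mlon = stats::median(.data$lon),
                          mlat = stats::median(.data$lat), .groups = "drop")
  ok_birds <- med$bird_id[
    med$mlat >= config$lat_box[1] & med$mlat <= config$lat_box[2] &
    med$mlon >= config$lon_box[1] & med$mlon <= config$lon_box[2]]
  fixes <- fixes[fixes$bird_id %in% ok_birds, ]
  note_stage("winter_box", before, fixes)
  if (nrow(fixes) == 0) warning("no fixes left after winter-box filter")

  # stage 2: non-breeding season months
  before <- fixes
  mo <- as.integer(format(fixes$timestamp, "%m"))
  fixes <- fixes[mo %in% config$season_months, ]
  note_stage("season", before, fixes)

  # stage 3: sampling-interval thinning (> min_dt from last kept fix)
  before <- fixes
  if (nrow(fixes)) {
    fixes <- fixes[order(fixes$bird_id, fixes$timestamp), ]
    keep <- unlist(lapply(split(as.numeric(fixes$timestamp) / 60, fixes$bird_id),
                          .thin_bird, min_dt = config$min_dt_min),
                   use.names = FALSE)
    fixes <- fixes[keep, ]
  }
  fixes <- annotate_kinematics(fixes, gap_flag_min = config$max_dt_min)
  note_stage("sampling_interval", before, fixes)

  # stage 4: speed ceiling. A forward relinking sweep per bird drops any fix
  # whose speed from the last *kept* fix exceeds the ceiling, so a single
  # displaced fix is removed without sacrificing its successor; the sweep is
  # repeated to a fixed point (it converges in one pass, the cap is a guard).
  before <- fixes
  for (pass in seq_len(10)) {
    if (!nrow(fixes)) break
    keep <- unlist(lapply(split(seq_len(nrow(fixes)), fixes$bird_id),
                          function(idx) .speed_sweep(
                            as.numeric(fixes$timestamp[idx]) / 60,
                            fixes$lon[idx], fixes$lat[idx],
                            config$max_speed_kmh)),
                   use.names = FALSE)
    done <- all(keep)
    fixes <- annotate_kinematics(fixes[keep, ],
                                 gap_flag_min = config$max_dt_min)
    if (done) break
  }
  note_stage("speed", before, fixes)

  # stage 5: minimum fixes per bird-year
  before <- fixes
  if (nrow(fixes)) {
    by <- .season_start_year(fixes$timestamp)
    label <- paste0(fixes$bird_id, "-", by)
    n_by <- table(label)
    fixes <- fixes[n_by[label] >= config$min_fixes_per_birdyear, ]
  }
  note_stage("min_fixes", before, fixes)

  attr(fixes, "filter_report") <- list(
    stages = dplyr::bind_rows(stages),
    by_bird = dplyr::bind_rows(by_bird)
  )
  fixes
}

# September-December fixes belong to the season starting that calendar year;
# January-March fixes to the season started the year before.
.season_start_year <- function(timestamp) {
  mo <- as.integer(format(timestamp, "%m"))
  yr <- as.integer(format(timestamp, "%Y"))
  ifelse(mo >= 9L, yr, yr - 1L)
}

#' Split season-filtered fixes into bird-years
#'
#' A bird-year is one individual's fixes within one non-breeding season
#' (September 1 to March 31 spanning the year boundary); e.g. the bird-year
#' `"3029-2017"` runs from September 2017 to March 2018.
#'
#' @param fixes Season-filtered fix tibble.
#' @return The tibble with `season_start_year` and `birdyear` columns.
#' @export
split_bird_years <- function(fixes) {
  mo <- as.integer(format(fixes$timestamp, "%m"))
  if (any(mo %in% 4:8))
    stop("fixes outside the September-March season; apply the season filter first")
  fixes$season_start_year <- .season_start_year(fixes$timestamp)
  fixes$birdyear <- paste0(fixes$bird_id, "-", fixes$season_start_year)
  fixes
}

#' Write annotated fixes back to a Movebank-dialect CSV
#'
#' @param fixes Annotated fix tibble.
#' @param path Output path.
#' @param dialect Column mapping for the four core columns.
#' @export
write_fixes_csv <- function(fixes, path, dialect = movebank_dialect()) {
  out <- tibble::tibble(fixes$bird_id, format(fixes$timestamp, "%Y-%m-%d %H:%M:%S"),
                        fixes$lon, fixes$lat)
  names(out) <- c(dialect$bird_id, dialect$timestamp, dialect$lon, dialect$lat)
  for (col in c("dt_min", "dist_km", "speed_kmh", "segment_start",
                "node_id", "birdyear"))
    if (!is.null(fixes[[col]])) out[[col]] <- fixes[[col]]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
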