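# Direct (non-stop) flight extraction: segmentation of node-assigned,
# speed-annotated trajectories into flights between distinct nodes, and
# pooling into a weighted edge list.

#' Flight-extraction configuration
#'
#' @param fly_speed_kmh Speed at or above which a stork is considered flying;
#'   stationary is strictly below this cutoff.
#' @param max_gap_min Maximum time difference (minutes) allowed between any
#'   two consecutive fixes of a flight, including the steps to the bounding
#'   stationary fixes; longer gaps discard the candidate flight.
#' @return A `flight_config` list.
#' @export
flight_config <- function(fly_speed_kmh = 10, max_gap_min = 60) {
  stopifnot(fly_speed_kmh > 0, max_gap_min > 0)
  structure(list(fly_speed_kmh = fly_speed_kmh, max_gap_min = max_gap_min),
            class = "flight_config")
}

#' Extract direct flights from annotated, node-assigned fixes
#'
#' A fix is stationary iff its incoming speed is below `fly_speed_kmh` (the
#' first fix of a segment, which has no incoming speed, counts as stationary);
#' all other fixes are flying. A maximal run of flying fixes bounded by two
#' stationary fixes becomes a direct flight iff the preceding stationary fix
#' lies in node A, the following stationary fix lies in a different node B,
#' both are assigned, every inter-fix time difference within the bounded run
#' (including both bounding steps) is at most `max_gap_min` minutes, and the
#' run does not cross a transmission-gap segment boundary. Node crossings at
#' flying speed do not split a flight.
#'
#' @param fixes Tibble with `birdyear`, `timestamp`, `speed_kmh`,
#'   `segment_start`, `node_id`, time-ordered within bird-year.
#' @param config A [flight_config()].
#' @return Tibble of direct flights: `birdyear`, `origin_node_id`,
#'   `dest_node_id`, `start_time`, `end_time`, `n_flight_fixes`,
#'   `max_gap_min`.
#' @export
extract_direct_flights <- function(fixes, config = flight_config()) {
  needed <- c("birdyear", "timestamp", "dt_min", "speed_kmh", "segment_start",
              "node_id")
  missing <- setdiff(needed, names(fixes))
  if (length(missing))
    stop("fixes lack required annotation column(s): ",
         paste(missing, collapse = ", "))
  fixes <- fixes[order(fixes$birdyear, fixes$timestamp), ]
  out <- lapply(split(seq_len(nrow(fixes)), fixes$birdyear),
                function(idx) .extract_by(fixes[idx, ], config))
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(birdyear = character(), origin_node_id = integer(),
                          dest_node_id = integer(),
                          start_time = as.POSIXct(character(), tz = "UTC"),
                          end_time = as.POSIXct(character(), tz = "UTC"),
                          n_flight_fixes = integer(), max_gap_min = numeric())
  }
  res
}

.extract_by <- function(f, config) {
  n <- nrow(f)
  if (n < 3) return(NULL)
  # incoming speed of a segment-start fix is undefined -> stationary
  flying <- !is.na(f$speed_kmh) & !f$segment_start &
    f$speed_kmh >= config$fly_speed_kmh
  dt <- f$dt_min
  flights <- list()
  i <- 1L
  while (i <= n) {
    if (!flying[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && flying[j + 1L]) j <- j + 1L
    # run i..j of flying fixes; bounds are i-1 and j+1
    if (i > 1L && j < n) {
      ok <- TRUE
      # a segment boundary inside the bounded run means a >= max gap
      if (any(f$segment_start[i:(j + 1L)])) ok <- FALSE
      gaps <- dt[i:(j + 1L)]   # steps (i-1 -> i) ... (j -> j+1)
      if (ok && (anyNA(gaps) || any(gaps > config$max_gap_min))) ok <- FALSE
      a <- f$node_id[i - 1L]; b <- f$node_id[j + 1L]
      if (ok && !is.na(a) && !is.na(b) && a != b) {
        flights[[length(flights) + 1L]] <- tibble::tibble(
          birdyear = f$birdyear[i],
          origin_node_id = as.integer(a), dest_node_id = as.integer(b),
          start_time = f$timestamp[i - 1L], end_time = f$timestamp[j + 1L],
          n_flight_fixes = j - i + 1L, max_gap_min = max(gaps))
      }
    }
    i <- j + 1L
  }
  if (length(flights)) dplyr::bind_rows(flights) else NULL
}

#' Pool direct flights into a weighted directed edge list
#'
#' @param flights Tibble from [extract_direct_flights()].
#' @return Tibble `origin_node_id`, `dest_node_id`, `weight` (flight count),
#'   zero-weight pairs absent, sorted by origin then destination.
#' @export
flights_to_edgelist <- function(flights) {
  if (nrow(flights) == 0)
    return(tibble::tibble(origin_node_id = integer(), dest_node_id = integer(),
                          weight = integer()))
  el <- dplyr::count(flights, .data$origin_node_id, .data$dest_node_id,
                     name = "weight")
  el$weight <- as.integer(el$weight)
  dplyr::arrange(el, .data$origin_node_id, .data$dest_node_id)
}
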