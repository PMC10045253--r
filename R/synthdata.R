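# Synthetic landscapes, ground-truthed commuting trajectories and
# ERGM-distributed networks, so every pipeline stage can be validated
# without any telemetry download.

#' Landscape specification
#'
#' @param n_sites Named integer vector: number of sites per habitat class.
#' @param bbox Bounding box `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param radius_m Range of site radii in metres.
#' @param min_separation_km Minimum centre-to-centre separation; the default
#'   keeps sites farther apart than the 10-km node-merge radius so each site
#'   becomes its own network node.
#' @param seed Integer seed.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(n_sites = c("Landfills" = 3, "Marshes" = 3,
                                       "Rice fields" = 2),
                           bbox = c(-6.5, 36.2, -4.0, 38.0),
                           radius_m = c(300, 800),
                           min_separation_km = 12,
                           seed = 1L) {
  stopifnot(all(names(n_sites) %in% HABITAT_CLASSES), all(n_sites >= 0),
            length(bbox) == 4, bbox[1] < bbox[3], bbox[2] < bbox[4])
  structure(list(n_sites = n_sites, bbox = bbox, radius_m = radius_m,
                 min_separation_km = min_separation_km, seed = seed),
            class = "landscape_spec")
}

#' Generate a habitat landscape
#'
#' Places non-overlapping 24-gon sites by rejection sampling inside the
#' bounding box; deterministic given the spec's seed.
#'
#' @param spec A [landscape_spec()].
#' @return Habitat-polygon tibble (as [read_habitat_geojson()] returns), with
#'   extra columns `site_lon`, `site_lat`, `radius_m` recording the true
#'   centres.
#' @export
gen_landscape <- function(spec) {
  total <- sum(spec$n_sites)
  if (total == 0)
    return(tibble::tibble(polygon_id = character(), clc_code = integer(),
                          habitat = character(), geometry = list(),
                          site_lon = numeric(), site_lat = numeric(),
                          radius_m = numeric()))
  .with_seed(spec$seed, {
    centers <- matrix(NA_real_, total, 2)
    radii <- stats::runif(total, spec$radius_m[1], spec$radius_m[2])
    placed <- 0
    tries <- 0
    while (placed < total) {
      tries <- tries + 1
      if (tries > 1e4)
        stop("could not place ", total, " non-overlapping sites; ",
             "enlarge the bounding box or reduce min_separation_km")
      lon <- stats::runif(1, spec$bbox[1], spec$bbox[3])
      lat <- stats::runif(1, spec$bbox[2], spec$bbox[4])
      if (placed > 0) {
        d <- haversine_km(lon, lat, centers[seq_len(placed), 1],
                          centers[seq_len(placed), 2])
        if (min(d) < spec$min_separation_km) next
      }
      placed <- placed + 1
      centers[placed, ] <- c(lon, lat)
    }
    habs <- rep(names(spec$n_sites), spec$n_sites)
    rows <- lapply(seq_len(total), function(i) {
      ring <- .site_ring(centers[i, 1], centers[i, 2], radii[i])
      tibble::tibble(polygon_id = sprintf("site%03d", i),
                     clc_code = NA_integer_, habitat = habs[i],
                     geometry = list(list(ring)),
                     site_lon = centers[i, 1], site_lat = centers[i, 2],
                     radius_m = radii[i])
    })
    dplyr::bind_rows(rows)
  })
}

# regular 24-gon of radius r metres around (lon, lat)
.site_ring <- function(lon, lat, r_m, k = 24) {
  ang <- 2 * pi * (0:(k - 1)) / k
  ll <- laea_unproject(r_m * cos(ang), r_m * sin(ang), lon, lat)
  colnames(ll) <- c("lon", "lat")
  ll
}

#' Movement specification
#'
#' A two-state (dwell/transit) commuting model: birds dwell at sites with
#' log-normal dwell times, then fly in a straight line to the next site,
#' chosen with probability proportional to habitat preference times
#' exp(-distance/delta). Fixes arrive at a nominal 5-minute cadence with
#' timing jitter, Gaussian position noise and an optional daily
#' transmission-gap process.
#'
#' @param n_birds Number of birds.
#' @param season_start_year Non-breeding season starting year (season runs
#'   September 1 to March 31).
#' @param fix_interval_min Nominal fix cadence, minutes.
#' @param fix_jitter_s Uniform timing jitter, seconds (plus or minus).
#' @param dwell_median_h Median dwell time at a site, hours (log-normal).
#' @param dwell_sdlog Log-scale SD of the dwell distribution.
#' @param min_dwell_min Lower clamp on dwell times; guarantees at least one
#'   stationary fix between consecutive transits.
#' @param pref Named habitat preference weights (unlisted habitats get 1);
#'   the landfill-weighted default mimics landfill-centric commuting.
#' @param delta_km Distance-decay scale of site choice.
#' @param transit_speed_kmh Range of (constant per-trip) transit speeds.
#' @param gps_noise_m Gaussian position noise SD, metres.
#' @param gap_per_day Daily probability of a transmission gap.
#' @param gap_hours Range of gap durations, hours.
#' @param seed Integer seed.
#' @return A `movement_spec` list.
#' @export
movement_spec <- function(n_birds = 5, season_start_year = 2019,
                          fix_interval_min = 5, fix_jitter_s = 30,
                          dwell_median_h = 3, dwell_sdlog = 0.6,
                          min_dwell_min = 15,
                          pref = c("Landfills" = 3),
                          delta_km = 20,
                          transit_speed_kmh = c(25, 60),
                          gps_noise_m = 10,
                          gap_per_day = 0.05, gap_hours = c(2, 24),
                          seed = 1L) {
  stopifnot(transit_speed_kmh[1] > 10, n_birds >= 1)
  structure(list(n_birds = n_birds, season_start_year = season_start_year,
                 fix_interval_min = fix_interval_min,
                 fix_jitter_s = fix_jitter_s,
                 dwell_median_h = dwell_median_h, dwell_sdlog = dwell_sdlog,
                 min_dwell_min = min_dwell_min,
                 pref = pref, delta_km = delta_km,
                 transit_speed_kmh = transit_speed_kmh,
                 gps_noise_m = gps_noise_m,
                 gap_per_day = gap_per_day, gap_hours = gap_hours,
                 seed = seed),
            class = "movement_spec")
}

#' Generate commuting GPS tracks with ground truth
#'
#' @param landscape Tibble from [gen_landscape()] (needs `site_lon`,
#'   `site_lat`, `radius_m`).
#' @param spec A [movement_spec()].
#' @return List with `fixes` (bird_id, timestamp, lon, lat), `trips` (the
#'   ground-truth trip log: bird_id, origin_site, dest_site, depart, arrive)
#'   and `trip_matrix` (site-by-site trip counts).
#' @export
gen_tracks <- function(landscape, spec) {
  stopifnot(nrow(landscape) >= 2)
  ns <- nrow(landscape)
  prefs <- rep(1, ns)
  for (h in names(spec$pref)) prefs[landscape$habitat == h] <- spec$pref[[h]]
  dmat <- outer(seq_len(ns), seq_len(ns), function(i, j)
    haversine_km(landscape$site_lon[i], landscape$site_lat[i],
                 landscape$site_lon[j], landscape$site_lat[j]))
  t0 <- as.POSIXct(paste0(spec$season_start_year, "-09-01 00:00:00"), tz = "UTC")
  t_end <- as.POSIXct(paste0(spec$season_start_year + 1, "-03-31 23:59:59"), tz = "UTC")
  t_last_depart <- t_end - 24 * 3600   # transits begun after this are skipped
  jitter_r <- pmin(100, landscape$radius_m * 0.3)

  .with_seed(spec$seed, {
    all_fixes <- list()
    all_trips <- list()
    interval_s <- spec$fix_interval_min * 60
    for (bird in seq_len(spec$n_birds)) {
      bird_id <- sprintf("S%03d", bird)
      site <- sample.int(ns, 1, prob = prefs)
      t <- as.numeric(t0) + stats::runif(1, 0, interval_s)
      blocks <- list()
      # jittered fix times from `from`, first fix at `from`, spanning `span_s`
      # seconds plus one extra step (the caller trims)
      fix_times <- function(from, span_s) {
        k <- ceiling(span_s / (interval_s - spec$fix_jitter_s)) + 2
        dts <- interval_s + stats::runif(k, -spec$fix_jitter_s,
                                         spec$fix_jitter_s)
        from + c(0, cumsum(dts))
      }
      while (t <= as.numeric(t_end)) {
        # dwell: within-site jitter at far below flying speed
        dwell_s <- 60 * max(spec$min_dwell_min,
                            stats::rlnorm(1, log(spec$dwell_median_h * 60),
                                          spec$dwell_sdlog))
        tt <- fix_times(t, dwell_s)
        keep <- tt <= min(t + dwell_s, as.numeric(t_end))
        t_next <- tt[max(which(keep)) + 1]
        tt <- tt[keep]
        th <- stats::runif(length(tt), 0, 2 * pi)
        rr <- jitter_r[site] * sqrt(stats::runif(length(tt)))
        pos <- laea_unproject(rr * cos(th), rr * sin(th),
                              landscape$site_lon[site],
                              landscape$site_lat[site])
        blocks[[length(blocks) + 1]] <- cbind(tt, pos[, 1], pos[, 2])
        t <- t_next
        if (t > as.numeric(t_last_depart) || t > as.numeric(t_end)) break
        # transit: straight path at constant sampled speed
        w <- prefs * exp(-dmat[site, ] / spec$delta_km)
        w[site] <- 0
        dest <- sample.int(ns, 1, prob = w)
        speed <- stats::runif(1, spec$transit_speed_kmh[1],
                              spec$transit_speed_kmh[2])
        dist <- dmat[site, dest]
        depart <- t
        arrive <- depart + dist / speed * 3600
        tt <- fix_times(depart, arrive - depart)
        keep <- tt < arrive
        t_next <- tt[max(which(keep)) + 1]
        tt <- tt[keep]
        frac <- (tt - depart) / (arrive - depart)
        blocks[[length(blocks) + 1]] <- cbind(
          tt,
          landscape$site_lon[site] +
            frac * (landscape$site_lon[dest] - landscape$site_lon[site]),
          landscape$site_lat[site] +
            frac * (landscape$site_lat[dest] - landscape$site_lat[site]))
        all_trips[[length(all_trips) + 1]] <- tibble::tibble(
          bird_id = bird_id,
          origin_site = landscape$polygon_id[site],
          dest_site = landscape$polygon_id[dest],
          depart = as.POSIXct(depart, origin = "1970-01-01", tz = "UTC"),
          arrive = as.POSIXct(arrive, origin = "1970-01-01", tz = "UTC"))
        site <- dest
        t <- max(t_next, arrive)   # first dwell fix shortly after arrival
      }
      m <- do.call(rbind, blocks)
      fx <- tibble::tibble(
        bird_id = bird_id,
        timestamp = as.POSIXct(m[, 1], origin = "1970-01-01", tz = "UTC"),
        lon = m[, 2], lat = m[, 3])
      # GPS noise
      if (spec$gps_noise_m > 0) {
        dx <- stats::rnorm(nrow(fx), 0, spec$gps_noise_m)
        dy <- stats::rnorm(nrow(fx), 0, spec$gps_noise_m)
        fx$lat <- fx$lat + dy / 1000 / 111.195
        fx$lon <- fx$lon + dx / 1000 / (111.195 * cos(fx$lat * pi / 180))
      }
      # transmission gaps
      if (spec$gap_per_day > 0) {
        days <- seq(as.Date(t0), as.Date(t_end), by = "day")
        gap_day <- stats::runif(length(days)) < spec$gap_per_day
        for (d in which(gap_day)) {
          g0 <- as.POSIXct(paste(days[d], "00:00:00"), tz = "UTC") +
            stats::runif(1, 0, 24 * 3600)
          g1 <- g0 + stats::runif(1, spec$gap_hours[1], spec$gap_hours[2]) * 3600
          fx <- fx[fx$timestamp < g0 | fx$timestamp > g1, ]
        }
      }
      all_fixes[[bird]] <- fx
    }
    fixes <- dplyr::bind_rows(all_fixes)
    trips <- if (length(all_trips)) dplyr::bind_rows(all_trips) else
      tibble::tibble(bird_id = character(), origin_site = character(),
                     dest_site = character(),
                     depart = as.POSIXct(character(), tz = "UTC"),
                     arrive = as.POSIXct(character(), tz = "UTC"))
    tm <- matrix(0L, ns, ns,
                 dimnames = list(landscape$polygon_id, landscape$polygon_id))
    if (nrow(trips)) {
      tab <- table(trips$origin_site, trips$dest_site)
      tm[rownames(tab), colnames(tab)] <- tab
    }
    list(fixes = fixes, trips = trips, trip_matrix = tm)
  })
}

#' Generate an ERGM-distributed network
#'
#' Materializes a habitat assignment and a symmetric pairwise distance matrix
#' (uniform on `dist_range_km` unless supplied), then draws dyad counts
#' exactly from the valued ERGM at the given coefficients.
#'
#' @param habitat Character vector of node habitats.
#' @param terms Model terms (see [ergm_model()]); `"edgecov:distance_km"`
#'   uses the generated distance matrix.
#' @param theta Generating coefficients aligned with `terms`.
#' @param seed Integer seed (drives both the distances and the counts).
#' @param distance_km Optional symmetric distance matrix.
#' @param dist_range_km Range for the uniform random distances.
#' @return List with `network` (a `spatial_network`), `model` (the
#'   [ergm_model()]) and `theta`.
#' @export
gen_ergm_network <- function(habitat, terms, theta, seed = 1L,
                             distance_km = NULL, dist_range_km = c(2, 200)) {
  n <- length(habitat)
  if (is.null(distance_km)) {
    distance_km <- .with_seed(seed, {
      d <- matrix(0, n, n)
      d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, dist_range_km[1],
                                      dist_range_km[2])
      d + t(d)
    })
  }
  model <- ergm_model(terms, habitat,
                      covariates = list(distance_km = distance_km))
  net <- simulate_network(theta, model, seed = seed + 1L)
  net$distance_m <- distance_km * 1000
  list(network = net, model = model, theta = theta)
}

#' Regional coefficient and node-inventory presets
#'
#' Representative valued-ERGM configurations for the two regional stork
#' networks the package targets: a southern-Spain network of 34 sites with
#' landfills and all eight wetland classes, and a northern-Morocco network of
#' 31 sites where fish aquaculture, irrigation ponds, dams and salines are
#' absent. Coefficients are on the log-flights scale; the distance covariate
#' is in km.
#'
#' @param region `"southern_spain"` or `"northern_morocco"`.
#' @return List with `habitat` (node inventory), `terms` and `theta`.
#' @export
regional_ergm_config <- function(region = c("southern_spain",
                                            "northern_morocco")) {
  region <- match.arg(region)
  if (region == "southern_spain") {
    habitat <- rep(c("Landfills", "Rice fields", "Fish aquaculture",
                     "Irrigation ponds", "Dams", "Salines", "Marshes",
                     "Lakes and ponds", "Water courses", "Urban areas",
                     "Non-irrigated arable land", "Permanently irrigated land",
                     "Agro-forestry areas"),
                   c(5, 3, 3, 3, 3, 3, 3, 3, 3, 2, 1, 1, 1))
    terms <- c("sum", "nodeofactor:Landfills",
               "nodeifactor:Rice fields", "nodeifactor:Fish aquaculture",
               "nodeifactor:Irrigation ponds", "nodeifactor:Dams",
               "nodeifactor:Salines", "nodeifactor:Marshes",
               "nodeifactor:Lakes and ponds", "nodeifactor:Water courses",
               "edgecov:distance_km", "mutuality")
    theta <- c(4.75, 1.49, 2.53, -0.05, -2.32, -1.28, 1.66, -1.45, -0.06,
               0.04, -0.15, 0.85)
  } else {
    habitat <- rep(c("Landfills", "Rice fields", "Marshes", "Lakes and ponds",
                     "Water courses", "Urban areas",
                     "Non-irrigated arable land", "Permanently irrigated land",
                     "Agro-forestry areas"),
                   c(5, 4, 4, 4, 4, 3, 3, 2, 2))
    terms <- c("sum", "nodeofactor:Landfills",
               "nodeifactor:Rice fields", "nodeifactor:Marshes",
               "nodeifactor:Lakes and ponds", "nodeifactor:Water courses",
               "edgecov:distance_km", "mutuality")
    theta <- c(5.56, 0.39, 0.01, 0.08, -0.28, -0.78, -0.19, 0.08)
  }
  list(habitat = habitat, terms = terms,
       theta = stats::setNames(theta, terms))
}
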