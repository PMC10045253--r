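# Pipeline orchestration: a flat sectioned key-value config, stage
# subcommands, provenance records and seeded reproducibility.

#' Parse a pipeline configuration file
#'
#' Flat `key = value` text grouped by `[section]` headers; blank lines and
#' `#` comments ignored. Values are scalars; comma-separated lists are split;
#' numbers are converted when possible.
#'
#' @param path Config file.
#' @return Nested named list (section -> key -> value) with attribute
#'   `config_md5`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (grepl(",", val)) val <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    cfg[[section]][[key]] <- val
  }
  attr(cfg, "config_md5") <- unname(tools::md5sum(path))
  cfg
}

.cfg <- function(cfg, section, key, default = NULL) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

.provenance <- function(cfg, seed, stage, outputs) {
  list(stage = stage,
       package = "storknet",
       version = as.character(utils::packageVersion("storknet")),
       seed = seed,
       config_md5 = attr(cfg, "config_md5") %||% NA,
       outputs = basename(outputs))
}

.write_provenance <- function(prov, out_dir, stage) {
  path <- file.path(out_dir, paste0(stage, ".provenance.json"))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

# read back an annotated/assigned fixes CSV written by write_fixes_csv
.read_annotated_fixes <- function(path, dialect = movebank_dialect()) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(
    bird_id = as.character(x[[dialect$bird_id]]),
    timestamp = as.POSIXct(x[[dialect$timestamp]], tz = "UTC"),
    lon = x[[dialect$lon]], lat = x[[dialect$lat]])
  for (col in c("dt_min", "dist_km", "speed_kmh", "segment_start", "node_id",
                "birdyear"))
    if (col %in% names(x)) out[[col]] <- x[[col]]
  out
}

.filter_config_from <- function(cfg) {
  filter_config(
    lat_box = .cfg(cfg, "filter", "lat_box", c(30.0, 42.5)),
    lon_box = .cfg(cfg, "filter", "lon_box", c(-10.0, 3.5)),
    min_dt_min = .cfg(cfg, "filter", "min_dt_min", 4),
    max_dt_min = .cfg(cfg, "filter", "max_dt_min", 61),
    max_speed_kmh = .cfg(cfg, "filter", "max_speed_kmh", 100),
    min_fixes_per_birdyear = .cfg(cfg, "filter", "min_fixes_per_birdyear", 1000))
}

.site_config_from <- function(cfg) {
  ov <- .cfg(cfg, "sites", "min_birdyears_override", NULL)
  site_config(
    merge_km = .cfg(cfg, "sites", "merge_km", 10),
    shoreline_buffer_m = .cfg(cfg, "sites", "shoreline_buffer_m", 200),
    cutoff_lat_deg = .cfg(cfg, "sites", "cutoff_lat_deg", 38.0),
    min_birdyears_override = ov)
}

#' Run a pipeline stage
#'
#' Subcommands: `simulate-landscape`, `simulate-tracks`, `filter`,
#' `build-sites`, `extract-flights`, `build-network`, `metrics`, `modules`,
#' `habitat-network`, `ergm-fit`, `ergm-simulate`, `full-pipeline`. Each
#' writes its module's artifacts plus a JSON provenance record into
#' `out_dir`; on error, partial outputs of the failing stage are removed.
#'
#' @param subcommand Stage name.
#' @param config Path to a config file or a parsed config list.
#' @param out_dir Output directory (created if needed); overrides the config.
#' @param seed Integer seed; overrides the config.
#' @return Invisibly, the paths written.
#' @export
run_pipeline <- function(subcommand, config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) parse_config(config) else config
  out_dir <- out_dir %||% .cfg(cfg, "paths", "out_dir", "storknet-out")
  seed <- as.integer(seed %||% .cfg(cfg, "global", "seed", 1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- c("simulate-landscape", "simulate-tracks", "filter",
              "build-sites", "extract-flights", "build-network", "metrics",
              "modules", "habitat-network", "ergm-fit", "ergm-simulate")
  if (identical(subcommand, "full-pipeline")) {
    done <- character()
    for (s in setdiff(stages, "ergm-simulate"))
      done <- c(done, run_pipeline(s, cfg, out_dir, seed))
    return(invisible(done))
  }
  if (!subcommand %in% stages) stop("unknown subcommand: ", subcommand)
  fn <- switch(subcommand,
    "simulate-landscape" = .stage_sim_landscape,
    "simulate-tracks" = .stage_sim_tracks,
    "filter" = .stage_filter,
    "build-sites" = .stage_build_sites,
    "extract-flights" = .stage_extract_flights,
    "build-network" = .stage_build_network,
    "metrics" = .stage_metrics,
    "modules" = .stage_modules,
    "habitat-network" = .stage_habitat_network,
    "ergm-fit" = .stage_ergm_fit,
    "ergm-simulate" = .stage_ergm_simulate)
  outputs <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs), add = TRUE)
  outputs <- fn(cfg, out_dir, seed)
  prov <- .write_provenance(.provenance(cfg, seed, subcommand, outputs),
                            out_dir, subcommand)
  outputs <- c(outputs, prov)
  ok <- TRUE
  invisible(outputs)
}

.stage_sim_landscape <- function(cfg, out_dir, seed) {
  ns <- .cfg(cfg, "synth", "n_sites", c("Landfills:3", "Marshes:3", "Rice fields:2"))
  parts <- strsplit(ns, ":")
  n_sites <- stats::setNames(as.integer(vapply(parts, `[`, "", 2)),
                             vapply(parts, `[`, "", 1))
  spec <- landscape_spec(
    n_sites = n_sites,
    bbox = .cfg(cfg, "synth", "bbox", c(-6.5, 36.2, -4.0, 38.0)),
    radius_m = .cfg(cfg, "synth", "radius_m", c(300, 800)),
    min_separation_km = .cfg(cfg, "synth", "min_separation_km", 12),
    seed = seed)
  land <- gen_landscape(spec)
  p <- file.path(out_dir, "landscape.geojson")
  write_geojson(land, p)
  p
}

.stage_sim_tracks <- function(cfg, out_dir, seed) {
  land <- read_habitat_geojson(file.path(out_dir, "landscape.geojson"))
  spec <- movement_spec(
    n_birds = .cfg(cfg, "synth", "n_birds", 5),
    season_start_year = .cfg(cfg, "synth", "season_start_year", 2019),
    gps_noise_m = .cfg(cfg, "synth", "gps_noise_m", 10),
    gap_per_day = .cfg(cfg, "synth", "gap_per_day", 0.05),
    seed = seed)
  tr <- gen_tracks(land, spec)
  p1 <- file.path(out_dir, "fixes.csv")
  write_fixes_csv(tr$fixes, p1)
  p2 <- file.path(out_dir, "truth_trips.csv")
  readr::write_csv(tr$trips, p2, progress = FALSE)
  c(p1, p2)
}

.stage_filter <- function(cfg, out_dir, seed) {
  fixes_path <- .cfg(cfg, "paths", "fixes", file.path(out_dir, "fixes.csv"))
  fixes <- read_fixes(fixes_path)
  filtered <- filter_cascade(fixes, .filter_config_from(cfg))
  filtered <- split_bird_years(filtered)
  p1 <- file.path(out_dir, "fixes_filtered.csv")
  write_fixes_csv(filtered, p1)
  p2 <- file.path(out_dir, "filter_report.json")
  rep <- attr(filtered, "filter_report")
  jsonlite::write_json(list(stages = rep$stages, by_bird = rep$by_bird),
                       p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(p1, p2)
}

.stage_build_sites <- function(cfg, out_dir, seed) {
  sites_path <- .cfg(cfg, "paths", "sites",
                     file.path(out_dir, "landscape.geojson"))
  polys <- read_habitat_geojson(sites_path)
  no_hab <- is.na(polys$habitat)
  if (any(no_hab))
    polys$habitat[no_hab] <- reclassify_habitat(polys$clc_code[no_hab])
  nodes <- merge_nearby(polys, .site_config_from(cfg))
  fixes <- .read_annotated_fixes(file.path(out_dir, "fixes_filtered.csv"))
  fixes <- assign_fixes(fixes, nodes)
  nodes <- node_occupancy(fixes, nodes)
  nodes <- occupancy_filter(nodes, .site_config_from(cfg))
  fixes$node_id[!fixes$node_id %in% nodes$node_id] <- NA_integer_
  p1 <- file.path(out_dir, "nodes.geojson")
  write_geojson(nodes, p1)
  p2 <- file.path(out_dir, "node_table.csv")
  write_node_table(nodes, p2)
  p3 <- file.path(out_dir, "fixes_assigned.csv")
  write_fixes_csv(fixes, p3)
  c(p1, p2, p3)
}

.stage_extract_flights <- function(cfg, out_dir, seed) {
  fixes <- .read_annotated_fixes(file.path(out_dir, "fixes_assigned.csv"))
  config <- flight_config(
    fly_speed_kmh = .cfg(cfg, "flights", "fly_speed_kmh", 10),
    max_gap_min = .cfg(cfg, "flights", "max_gap_min", 60))
  fl <- extract_direct_flights(fixes, config)
  p1 <- file.path(out_dir, "flights.csv")
  readr::write_csv(fl, p1, progress = FALSE)
  p2 <- file.path(out_dir, "edgelist.csv")
  readr::write_csv(flights_to_edgelist(fl), p2, progress = FALSE)
  c(p1, p2)
}

.load_network <- function(out_dir) {
  nodes <- readr::read_csv(file.path(out_dir, "node_table.csv"),
                           show_col_types = FALSE, progress = FALSE)
  el <- readr::read_csv(file.path(out_dir, "edgelist.csv"),
                        show_col_types = FALSE, progress = FALSE)
  build_network(el, nodes)
}

.stage_build_network <- function(cfg, out_dir, seed) {
  net <- .load_network(out_dir)   # validates endpoints and weights
  p <- file.path(out_dir, "network_summary.json")
  jsonlite::write_json(list(n_nodes = nrow(net$nodes),
                            n_links = nrow(net$edges),
                            total_flights = sum(net$edges$weight)),
                       p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p
}

.stage_metrics <- function(cfg, out_dir, seed) {
  net <- .load_network(out_dir)
  p <- file.path(out_dir, "metrics.csv")
  readr::write_csv(node_metrics(net), p, progress = FALSE)
  p
}

.stage_modules <- function(cfg, out_dir, seed) {
  net <- .load_network(out_dir)
  part <- detect_modules(net, seed = seed,
                         n_restarts = .cfg(cfg, "mapeq", "n_restarts", 10),
                         tau = .cfg(cfg, "mapeq", "tau", 0.15))
  p1 <- file.path(out_dir, "partition.csv")
  readr::write_csv(tibble::tibble(node_id = as.integer(names(part$membership)),
                                  module = as.integer(part$membership)),
                   p1, progress = FALSE)
  p2 <- file.path(out_dir, "modules.json")
  jsonlite::write_json(list(codelength_bits = part$codelength_bits,
                            n_modules = part$n_modules, seed = part$seed,
                            tau = part$tau),
                       p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p3 <- file.path(out_dir, "module_hulls.geojson")
  write_geojson(module_hulls(part, net), p3)
  c(p1, p2, p3)
}

.stage_habitat_network <- function(cfg, out_dir, seed) {
  net <- .load_network(out_dir)
  hn <- aggregate_by_habitat(net)
  p <- file.path(out_dir, "habitat_network.csv")
  readr::write_csv(hn, p, progress = FALSE)
  p
}

.ergm_model_from <- function(cfg, net) {
  terms <- .cfg(cfg, "ergm", "terms",
                c("sum", "nodeofactor:Landfills", "edgecov:distance_km",
                  "mutuality"))
  ergm_model(terms, net$nodes$habitat,
             covariates = list(distance_km = net$distance_m / 1000))
}

.stage_ergm_fit <- function(cfg, out_dir, seed) {
  net <- .load_network(out_dir)
  model <- .ergm_model_from(cfg, net)
  fit <- fit_mle(net, model)
  p1 <- file.path(out_dir, "ergm_fit.json")
  jsonlite::write_json(list(coefficients = fit$coefficients,
                            loglik = fit$loglik, converged = fit$converged,
                            iterations = fit$iterations),
                       p1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p2 <- file.path(out_dir, "ergm_table.txt")
  utils::capture.output(print(fit), file = p2)
  c(p1, p2)
}

.stage_ergm_simulate <- function(cfg, out_dir, seed) {
  region <- .cfg(cfg, "ergm", "region", "southern_spain")
  conf <- regional_ergm_config(region)
  sim <- gen_ergm_network(conf$habitat, conf$terms, conf$theta, seed = seed)
  p <- file.path(out_dir, "ergm_simulated_edgelist.csv")
  readr::write_csv(sim$network$edges, p, progress = FALSE)
  p
}
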