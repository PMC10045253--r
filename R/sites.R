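# Network nodes from habitat polygons: Corine reclassification, 10-km
# same-habitat merging, shoreline buffering, fix-to-node assignment and the
# bird-year occupancy cutoff.

#' The 14 habitat classes
#'
#' Three urban surfaces, three agricultural terrestrial habitats, five
#' artificial and three natural wetland habitats.
#' @export
HABITAT_CLASSES <- c(
  "Landfills", "Urban areas", "Golf course",
  "Agro-forestry areas", "Non-irrigated arable land", "Permanently irrigated land",
  "Rice fields", "Fish aquaculture", "Irrigation ponds", "Dams", "Salines",
  "Marshes", "Lakes and ponds", "Water courses"
)

#' The eight wetland classes (shoreline-buffer eligible)
#' @export
WETLAND_CLASSES <- c(
  "Rice fields", "Fish aquaculture", "Irrigation ponds", "Dams", "Salines",
  "Marshes", "Lakes and ponds", "Water courses"
)

# Corine Land Cover code -> habitat label. Codes 422 and 512 map to several
# labels; the first listed is the default and the alternatives require an
# explicit override. Code 131 (mineral extraction sites) is treated as
# Landfills: dump sites are routinely misclassified as mineral extraction in
# CLC and are recognisable from the concentration of GPS fixes.
.CLC_MAP <- list(
  `111` = "Urban areas", `112` = "Urban areas", `121` = "Urban areas",
  `131` = "Landfills", `132` = "Landfills",
  `142` = "Golf course",
  `211` = "Non-irrigated arable land", `212` = "Permanently irrigated land",
  `213` = "Rice fields", `244` = "Agro-forestry areas",
  `411` = "Marshes", `421` = "Marshes",
  `422` = c("Salines", "Fish aquaculture"),
  `511` = "Water courses",
  `512` = c("Lakes and ponds", "Dams", "Irrigation ponds")
)

#' Reclassify a Corine Land Cover code to a habitat class
#'
#' @param clc_code Integer CLC code(s).
#' @param override Optional habitat label(s) overriding the default mapping;
#'   required to select the non-default label of multi-label codes (422 can be
#'   Salines or Fish aquaculture; 512 can be Lakes and ponds, Dams or
#'   Irrigation ponds). `NA` entries fall back to the default.
#' @return Character vector of habitat labels.
#' @export
reclassify_habitat <- function(clc_code, override = NULL) {
  n <- length(clc_code)
  if (is.null(override)) override <- rep(NA_character_, n)
  override <- rep_len(as.character(override), n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (!is.na(override[i])) {
      if (!override[i] %in% HABITAT_CLASSES)
        stop("unknown habitat override: ", override[i])
      out[i] <- override[i]
      next
    }
    key <- as.character(clc_code[i])
    labels <- .CLC_MAP[[key]]
    if (is.null(labels))
      stop("unknown CLC code without habitat override: ", key)
    out[i] <- labels[1]
  }
  out
}

#' Site-selection configuration
#'
#' @param merge_km Same-habitat polygons closer than this are merged into one
#'   node (boundary-to-boundary distance).
#' @param shoreline_buffer_m Outward buffer applied to wetland polygons before
#'   merging (the shoreline is favoured habitat). The source study does not
#'   state its width; 200 m is this package's default.
#' @param cutoff_lat_deg The occupancy threshold is the median bird-year count
#'   over candidate nodes at or below this latitude (the core wintering area).
#' @param min_birdyears_override Explicit occupancy threshold overriding the
#'   median rule.
#' @param boundary_step_m Perimeter sampling step for boundary distances.
#' @return A `site_config` list.
#' @export
site_config <- function(merge_km = 10, shoreline_buffer_m = 200,
                        cutoff_lat_deg = 38.0, min_birdyears_override = NULL,
                        boundary_step_m = 100) {
  stopifnot(merge_km > 0, shoreline_buffer_m >= 0)
  structure(list(merge_km = merge_km, shoreline_buffer_m = shoreline_buffer_m,
                 cutoff_lat_deg = cutoff_lat_deg,
                 min_birdyears_override = min_birdyears_override,
                 boundary_step_m = boundary_step_m),
            class = "site_config")
}

#' Buffer the shoreline of a wetland polygon
#'
#' Dilates every ring of a wetland polygon outward by a metric distance
#' (Minkowski sum with a disk, computed in a local equal-area projection;
#' corner arcs are discretised). Only the eight wetland classes are eligible.
#'
#' @param rings Multipolygon (list of lon/lat rings).
#' @param habitat Habitat label of the polygon.
#' @param buffer_m Buffer width in metres.
#' @return Buffered multipolygon.
#' @export
buffer_shoreline <- function(rings, habitat, buffer_m) {
  if (!habitat %in% WETLAND_CLASSES)
    stop("shoreline buffering applies to wetland habitats only, got: ", habitat)
  if (buffer_m == 0) return(rings)
  lapply(rings, function(r) {
    lon0 <- mean(range(r[, 1])); lat0 <- mean(range(r[, 2]))
    pr <- laea_project(r[, 1], r[, 2], lon0, lat0)
    off <- offset_ring_planar(pr, buffer_m)
    ll <- laea_unproject(off[, 1], off[, 2], lon0, lat0)
    colnames(ll) <- c("lon", "lat")
    ll
  })
}

#' Merge nearby same-habitat polygons into site nodes
#'
#' Single-linkage clustering within each habitat class: polygons whose
#' boundaries (sampled every `boundary_step_m` metres) lie within `merge_km`
#' kilometres of each other end up in one node. Node ids are assigned
#' deterministically by centroid latitude, then longitude.
#'
#' @param polygons Habitat-polygon tibble with a filled `habitat` column.
#' @param config A [site_config()]; wetland polygons are shoreline-buffered
#'   before merging.
#' @return Site-node tibble: `node_id`, `habitat`, `centroid_lon`,
#'   `centroid_lat`, `n_polygons`, `geometry` (merged multipolygon).
#' @export
merge_nearby <- function(polygons, config = site_config()) {
  stopifnot(all(!is.na(polygons$habitat)),
            all(polygons$habitat %in% HABITAT_CLASSES))
  geoms <- polygons$geometry
  wet <- polygons$habitat %in% WETLAND_CLASSES
  if (config$shoreline_buffer_m > 0) {
    for (i in which(wet))
      geoms[[i]] <- buffer_shoreline(geoms[[i]], polygons$habitat[i],
                                     config$shoreline_buffer_m)
  }
  nodes <- list()
  for (hab in unique(polygons$habitat)) {
    idx <- which(polygons$habitat == hab)
    k <- length(idx)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (k > 1) {
      # centroid-distance prefilter bounds the boundary distance from below
      cents <- t(vapply(geoms[idx], multipolygon_centroid, numeric(2)))
      radii <- vapply(geoms[idx], function(g) {
        cc <- multipolygon_centroid(g)
        max(haversine_km(cc[1], cc[2],
                         do.call(rbind, g)[, 1], do.call(rbind, g)[, 2]))
      }, numeric(1))
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        lower <- haversine_km(cents[i, 1], cents[i, 2], cents[j, 1], cents[j, 2]) -
          radii[i] - radii[j]
        if (lower > config$merge_km) next
        d <- min_boundary_distance_km(geoms[[idx[i]]], geoms[[idx[j]]],
                                      step_m = config$boundary_step_m)
        if (d <= config$merge_km) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    roots <- vapply(seq_len(k), find, integer(1))
    for (r in unique(roots)) {
      members <- idx[roots == r]
      merged <- do.call(c, geoms[members])
      cc <- multipolygon_centroid(merged)
      nodes[[length(nodes) + 1]] <- tibble::tibble(
        habitat = hab, centroid_lon = cc[1], centroid_lat = cc[2],
        n_polygons = length(members), geometry = list(merged))
    }
  }
  nodes <- dplyr::bind_rows(nodes)
  nodes <- nodes[order(nodes$centroid_lat, nodes$centroid_lon), ]
  nodes$node_id <- seq_len(nrow(nodes))
  nodes[, c("node_id", "habitat", "centroid_lon", "centroid_lat",
            "n_polygons", "geometry")]
}

#' Assign GPS fixes to site nodes
#'
#' Point-in-polygon on WGS84 coordinates; boundary points count as inside.
#' When buffered nodes overlap, the smallest node id wins (a warning is
#' emitted once).
#'
#' @param fixes Fix tibble.
#' @param nodes Site-node tibble from [merge_nearby()].
#' @return The fix tibble with a `node_id` column (`NA` outside all nodes).
#' @export
assign_fixes <- function(fixes, nodes) {
  n <- nrow(fixes)
  node_id <- rep(NA_integer_, n)
  overlap_seen <- FALSE
  ord <- order(nodes$node_id)
  for (i in ord) {
    rings <- nodes$geometry[[i]]
    bb <- apply(do.call(rbind, rings), 2, range)
    cand <- which(fixes$lon >= bb[1, 1] & fixes$lon <= bb[2, 1] &
                  fixes$lat >= bb[1, 2] & fixes$lat <= bb[2, 2])
    if (!length(cand)) next
    hit <- cand[point_in_multipolygon(fixes$lon[cand], fixes$lat[cand], rings)]
    clash <- hit[!is.na(node_id[hit])]
    if (length(clash) && !overlap_seen &&
        any(nodes$habitat[match(node_id[clash], nodes$node_id)] != nodes$habitat[i])) {
      warning("overlapping nodes of different habitat; smallest node_id wins")
      overlap_seen <- TRUE
    }
    free <- hit[is.na(node_id[hit])]
    node_id[free] <- nodes$node_id[i]
  }
  fixes$node_id <- node_id
  fixes
}

#' Count bird-years using each node
#'
#' A bird-year uses a node if at least one of its fixes is assigned there.
#'
#' @param fixes Node-assigned fix tibble with a `birdyear` column.
#' @param nodes Site-node tibble.
#' @return The node tibble with a `birdyear_count` column.
#' @export
node_occupancy <- function(fixes, nodes) {
  used <- unique(fixes[!is.na(fixes$node_id), c("node_id", "birdyear")])
  counts <- table(used$node_id)
  nodes$birdyear_count <- as.integer(counts[as.character(nodes$node_id)])
  nodes$birdyear_count[is.na(nodes$birdyear_count)] <- 0L
  nodes
}

#' Apply the bird-year occupancy cutoff
#'
#' The threshold is the median bird-year count over candidate nodes with
#' centroid latitude at or below `cutoff_lat_deg` (for an even number of
#' candidates, the lower of the two middle values), applied network-wide;
#' or an explicit override.
#'
#' @param nodes Node tibble with `birdyear_count` (see [node_occupancy()]).
#' @param config A [site_config()].
#' @return Retained nodes, with the threshold in attribute
#'   `occupancy_threshold`.
#' @export
occupancy_filter <- function(nodes, config = site_config()) {
  thr <- config$min_birdyears_override
  if (is.null(thr)) {
    cand <- nodes$birdyear_count[nodes$centroid_lat <= config$cutoff_lat_deg]
    if (!length(cand))
      stop("no candidate nodes at or below latitude ", config$cutoff_lat_deg,
           " degrees; supply min_birdyears_override")
    s <- sort(cand)
    nn <- length(s)
    thr <- if (nn %% 2 == 1) s[(nn + 1) / 2] else s[nn / 2]
  }
  out <- nodes[nodes$birdyear_count >= thr, ]
  attr(out, "occupancy_threshold") <- thr
  out
}

#' Write a node table CSV
#' @param nodes Site-node tibble.
#' @param path Output path.
#' @export
write_node_table <- function(nodes, path) {
  readr::write_csv(nodes[, setdiff(names(nodes), "geometry")], path,
                   progress = FALSE)
  invisible(path)
}
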