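# GeoJSON input/output for habitat polygons and site nodes.
#
# Habitat polygons travel as a tibble with one row per polygon:
#   polygon_id (chr), clc_code (int or NA), habitat (chr or NA),
#   geometry (list column; each element a list of lon/lat rings).

#' Read habitat polygons from a GeoJSON FeatureCollection
#'
#' Features must be Polygon or MultiPolygon. Recognised properties are
#' `polygon_id`, `clc_code` (Corine Land Cover code) and `habitat` (an
#' explicit class label overriding the code-based reclassification).
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble of habitat polygons with a `geometry` list column.
#' @export
read_habitat_geojson <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  feats <- gj$features
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(.coords_to_ring(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(p) .coords_to_ring(p[[1]])),
      stop("feature ", i, ": unsupported geometry type ", geom$type)
    )
    props <- f$properties
    row <- tibble::tibble(
      polygon_id = as.character(props$polygon_id %||% i),
      clc_code = as.integer(props$clc_code %||% NA_integer_),
      habitat = as.character(props$habitat %||% NA_character_),
      geometry = list(rings)
    )
    # carry any extra scalar properties through (e.g. true site centres of
    # synthetic landscapes)
    extra <- setdiff(names(props), c("polygon_id", "clc_code", "habitat"))
    for (nm in extra) {
      v <- props[[nm]]
      if (is.atomic(v) && length(v) == 1) row[[nm]] <- v
    }
    row
  })
  dplyr::bind_rows(rows)
}

.coords_to_ring <- function(coords) {
  m <- matrix(unlist(coords), ncol = 2, byrow = TRUE)
  # drop the closing vertex if the ring is explicitly closed
  n <- nrow(m)
  if (n > 1 && all(abs(m[1, ] - m[n, ]) < 1e-12)) m <- m[-n, , drop = FALSE]
  colnames(m) <- c("lon", "lat")
  m
}

.ring_to_coords <- function(ring) {
  closed <- rbind(ring, ring[1, , drop = FALSE])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

#' Write habitat polygons or site nodes to GeoJSON
#'
#' @param x A habitat-polygon tibble (from [read_habitat_geojson()] or
#'   [gen_landscape()]) or a site-node tibble (from [merge_nearby()]).
#' @param path Output path.
#' @export
write_geojson <- function(x, path) {
  feats <- lapply(seq_len(nrow(x)), function(i) {
    rings <- x$geometry[[i]]
    geom <- if (length(rings) == 1L) {
      list(type = "Polygon", coordinates = list(.ring_to_coords(rings[[1]])))
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(rings, function(r) list(.ring_to_coords(r))))
    }
    props <- as.list(x[i, setdiff(names(x), "geometry"), drop = FALSE])
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA, pretty = FALSE, na = "null"
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
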