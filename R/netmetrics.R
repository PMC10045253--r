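# The spatial network and its metrics: assembly, in/out strength,
# distance-weighted betweenness, habitat-level aggregation, rank reports.

#' Build a spatial network from nodes and an edge list
#'
#' A directed network whose integer edge weights are direct-flight counts and
#' whose node attributes are habitat and centroid. The matrix of pairwise
#' centroid great-circle distances (metres) is computed on construction.
#'
#' @param edgelist Tibble `origin_node_id`, `dest_node_id`, `weight`.
#' @param nodes Site-node tibble (`node_id`, `habitat`, `centroid_lon`,
#'   `centroid_lat`, ...).
#' @return A `spatial_network` object: list with `nodes`, `edges`,
#'   `distance_m`.
#' @export
build_network <- function(edgelist, nodes) {
  stopifnot(nrow(nodes) > 0)
  dangling <- unique(c(
    setdiff(edgelist$origin_node_id, nodes$node_id),
    setdiff(edgelist$dest_node_id, nodes$node_id)))
  if (length(dangling))
    stop("edge endpoint(s) not among nodes: ", paste(dangling, collapse = ", "))
  if (any(edgelist$origin_node_id == edgelist$dest_node_id))
    stop("self-loop edges are not allowed")
  if (nrow(edgelist) && any(edgelist$weight < 1))
    stop("edge weights must be positive integers")
  nodes <- nodes[order(nodes$node_id), ]
  n <- nrow(nodes)
  dist_m <- outer(seq_len(n), seq_len(n), function(i, j)
    haversine_km(nodes$centroid_lon[i], nodes$centroid_lat[i],
                 nodes$centroid_lon[j], nodes$centroid_lat[j]) * 1000)
  diag(dist_m) <- 0
  dimnames(dist_m) <- list(nodes$node_id, nodes$node_id)
  structure(list(nodes = nodes,
                 edges = tibble::as_tibble(edgelist),
                 distance_m = dist_m),
            class = "spatial_network")
}

#' @export
print.spatial_network <- function(x, ...) {
  cat("<spatial_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " valued links, total weight ", sum(x$edges$weight), "\n", sep = "")
  invisible(x)
}

.as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(network$edges$origin_node_id),
               to = as.character(network$edges$dest_node_id),
               weight = network$edges$weight),
    directed = TRUE,
    vertices = data.frame(name = as.character(network$nodes$node_id)))
  g
}

#' Node strength (in or out)
#'
#' Sum of link values entering (`"in"`) or leaving (`"out"`) each node.
#'
#' @param network A `spatial_network`.
#' @param direction `"in"` or `"out"`.
#' @return Named integer vector over all nodes (zeros for isolates).
#' @export
strength <- function(network, direction = c("in", "out")) {
  direction <- match.arg(direction)
  ids <- network$nodes$node_id
  s <- stats::setNames(integer(length(ids)), ids)
  key <- if (direction == "in") network$edges$dest_node_id else network$edges$origin_node_id
  agg <- tapply(network$edges$weight, key, sum)
  s[names(agg)] <- as.integer(agg)
  s
}

#' Distance-weighted betweenness centrality
#'
#' Directed shortest-path betweenness with edge cost equal to the
#' great-circle distance between node centroids (metres). For each ordered
#' pair (s, t) every intermediate node v accrues the fraction of minimum-cost
#' s-t paths through v; unreachable pairs contribute nothing. Unnormalized.
#' Flight counts play no role in the path cost.
#'
#' @param network A `spatial_network`.
#' @return Named numeric vector over all nodes.
#' @export
betweenness <- function(network) {
  ids <- as.character(network$nodes$node_id)
  if (nrow(network$edges) == 0)
    return(stats::setNames(numeric(length(ids)), ids))
  g <- .as_igraph(network)
  w <- network$distance_m[cbind(as.character(network$edges$origin_node_id),
                                as.character(network$edges$dest_node_id))]
  b <- igraph::betweenness(g, directed = TRUE, weights = w, normalized = FALSE)
  stats::setNames(as.numeric(b[ids]), ids)
}

#' Per-node metric table
#'
#' @param network A `spatial_network`.
#' @return Tibble `node_id`, `habitat`, `centroid_lon`, `centroid_lat`,
#'   `betweenness`, `strength_in`, `strength_out`.
#' @export
node_metrics <- function(network) {
  tibble::tibble(
    node_id = network$nodes$node_id,
    habitat = network$nodes$habitat,
    centroid_lon = network$nodes$centroid_lon,
    centroid_lat = network$nodes$centroid_lat,
    betweenness = as.numeric(betweenness(network)),
    strength_in = as.integer(strength(network, "in")),
    strength_out = as.integer(strength(network, "out"))
  )
}

#' Aggregate the spatial network to habitat level
#'
#' Sums direct flights over all node pairs sharing the same (unordered)
#' habitat pair, yielding an undirected habitat network. Same-habitat pairs
#' appear as self-links.
#'
#' @param network A `spatial_network`.
#' @return Tibble `habitat_a`, `habitat_b` (alphabetical within pair),
#'   `weight`, absent when zero; attribute `total_weight` and
#'   `total_weight_no_self` record the grand totals with and without
#'   self-links.
#' @export
aggregate_by_habitat <- function(network) {
  hab <- stats::setNames(network$nodes$habitat, network$nodes$node_id)
  if (nrow(network$edges) == 0) {
    out <- tibble::tibble(habitat_a = character(), habitat_b = character(),
                          weight = integer())
    attr(out, "total_weight") <- 0L
    attr(out, "total_weight_no_self") <- 0L
    return(out)
  }
  ha <- hab[as.character(network$edges$origin_node_id)]
  hb <- hab[as.character(network$edges$dest_node_id)]
  a <- pmin(ha, hb); b <- pmax(ha, hb)
  agg <- tapply(network$edges$weight, paste(a, b, sep = "\r"), sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- tibble::tibble(
    habitat_a = vapply(parts, `[`, "", 1),
    habitat_b = vapply(parts, `[`, "", 2),
    weight = as.integer(agg))
  out <- dplyr::arrange(out, dplyr::desc(.data$weight), .data$habitat_a)
  attr(out, "total_weight") <- sum(out$weight)
  attr(out, "total_weight_no_self") <-
    sum(out$weight[out$habitat_a != out$habitat_b])
  out
}

#' Ranked metric report
#'
#' Top-k tables by betweenness and strength, and habitat links ranked by
#' flight count; deterministic ordering with ties broken by node id.
#'
#' @param metrics Tibble from [node_metrics()].
#' @param habitat_network Tibble from [aggregate_by_habitat()].
#' @param k Number of rows per table.
#' @return Named list of tibbles: `betweenness`, `strength_in`,
#'   `strength_out`, `habitat_links`.
#' @export
rank_report <- function(metrics, habitat_network, k = 10) {
  top <- function(col) {
    o <- order(-metrics[[col]], metrics$node_id)
    metrics[utils::head(o, k), c("node_id", "habitat", col)]
  }
  list(
    betweenness = top("betweenness"),
    strength_in = top("strength_in"),
    strength_out = top("strength_out"),
    habitat_links = utils::head(habitat_network, k)
  )
}
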