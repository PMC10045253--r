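# Independent oracles used by the unit and acceptance tests. Each is a
# deliberately naive re-derivation (brute force, closed form, dense linear
# algebra) kept separate from the package's own computation paths.

# spherical law of cosines distance (km), R = 6371.0088
slc_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  6371.0088 * acos(pmin(1, pmax(-1,
    sin(lat1 * r) * sin(lat2 * r) +
      cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r))))
}

# exhaustive-path betweenness: enumerate all simple paths per ordered pair,
# keep minimum-cost ones, share the pair's unit among intermediates
brute_betweenness <- function(n, edges, cost) {
  # edges: matrix (from, to); cost: vector aligned with edges
  adj <- lapply(seq_len(n), function(i) which(edges[, 1] == i))
  bet <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- list()
    costs <- numeric()
    dfs <- function(v, visited, cst, path) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- path
        costs[length(costs) + 1] <<- cst
        return()
      }
      for (e in adj[[v]]) {
        w <- edges[e, 2]
        if (!visited[w]) {
          vis <- visited; vis[w] <- TRUE
          dfs(w, vis, cst + cost[e], c(path, w))
        }
      }
    }
    vis0 <- logical(n); vis0[s] <- TRUE
    dfs(s, vis0, 0, s)
    if (!length(paths)) next
    mn <- min(costs)
    best <- paths[abs(costs - mn) <= 1e-9 * max(1, mn)]
    for (p in best) {
      mid <- setdiff(p, c(s, t))
      bet[mid] <- bet[mid] + 1 / length(best)
    }
  }
  bet
}

# dense stationary distribution of the teleported walk (left eigenvector)
eigen_flow <- function(W, tau) {
  n <- nrow(W)
  s <- rowSums(W)
  P <- W / ifelse(s > 0, s, 1)
  P[s == 0, ] <- 1 / n
  G <- tau / n + (1 - tau) * P
  ev <- eigen(t(G))
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  v / sum(v)
}

# direct evaluation of the two-level map equation from its definition
oracle_codelength <- function(part, W, tau) {
  n <- nrow(W)
  p <- eigen_flow(W, tau)
  s <- rowSums(W)
  P <- W / ifelse(s > 0, s, 1)
  P[s == 0, ] <- 1 / n    # dangling nodes behave like teleporters
  mods <- unique(part)
  q <- numeric(length(mods))
  plogp <- function(x) { x <- x[x > 0]; sum(x * log2(x)) }
  L <- 0
  for (k in seq_along(mods)) {
    inm <- part == mods[k]
    exit_link <- (1 - tau) * sum(p[inm] * rowSums(P[inm, !inm, drop = FALSE]))
    exit_tele <- tau * sum(p[inm]) * sum(!inm) / n
    q[k] <- exit_link + exit_tele
    pm <- q[k] + sum(p[inm])
    L <- L - pm * plogp(c(q[k], p[inm]) / pm)
  }
  Q <- sum(q)
  if (Q > 0) L <- L - Q * plogp(q / Q)
  L
}

# all set partitions of 1..n as a list of membership vectors (restricted
# growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(i, memb, kmax) {
    if (i > n) {
      out[[length(out) + 1]] <<- memb
      return()
    }
    for (m in seq_len(kmax + 1)) {
      memb[i] <- m
      rec(i + 1, memb, max(kmax, m))
    }
  }
  rec(1, integer(n), 0)
  out
}

# brute-force valued-ERGM sufficient statistics via a double loop
brute_stats <- function(y, habitat, terms, covariates = list()) {
  n <- nrow(y)
  g <- numeric(length(terms))
  for (k in seq_along(terms)) {
    tm <- terms[k]
    kind <- sub(":.*$", "", tm)
    arg <- sub("^[^:]+:", "", tm)
    acc <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      acc <- acc + switch(kind,
        sum = y[i, j],
        nodeofactor = y[i, j] * (habitat[i] == arg),
        nodeifactor = y[i, j] * (habitat[j] == arg),
        edgecov = y[i, j] * covariates[[arg]][i, j],
        mutuality = if (i < j) -abs(y[i, j] - y[j, i]) else 0)
    }
    g[k] <- acc
  }
  g
}

# high-cap double-sum log partition for one dyad
brute_log_partition <- function(e1, e2, thm, cap = 200) {
  a <- 0:cap
  lt <- outer(a, a, function(x, y)
    x * e1 + y * e2 - thm * abs(x - y) - lfactorial(x) - lfactorial(y))
  m <- max(lt)
  m + log(sum(exp(lt - m)))
}

# small helper: directed spatial network from explicit pieces
toy_network <- function(n, edges, lon = NULL, lat = NULL,
                        habitat = rep("Landfills", n)) {
  nodes <- tibble::tibble(
    node_id = seq_len(n), habitat = habitat,
    centroid_lon = lon %||% (seq_len(n) / 10),
    centroid_lat = lat %||% (40 + seq_len(n) / 10))
  el <- tibble::tibble(origin_node_id = edges[, 1], dest_node_id = edges[, 2],
                       weight = edges[, 3])
  build_network(el, nodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared small synthetic track scenario (built once per test run)
track_scenario <- function(noise_m = 0, gap_per_day = 0, n_birds = 2,
                           seed = 11) {
  land <- gen_landscape(landscape_spec(
    n_sites = c("Landfills" = 2, "Marshes" = 2, "Rice fields" = 1),
    seed = 3))
  tr <- gen_tracks(land, movement_spec(n_birds = n_birds,
                                       gps_noise_m = noise_m,
                                       gap_per_day = gap_per_day,
                                       seed = seed))
  nodes <- merge_nearby(land, site_config(shoreline_buffer_m = 0))
  site2node <- vapply(seq_len(nrow(land)), function(i)
    nodes$node_id[which.min(haversine_km(land$site_lon[i], land$site_lat[i],
                                         nodes$centroid_lon,
                                         nodes$centroid_lat))], integer(1))
  names(site2node) <- land$polygon_id
  list(land = land, tracks = tr, nodes = nodes, site2node = site2node)
}

# truth trip matrix re-indexed by node id
truth_matrix <- function(sc) {
  nn <- nrow(sc$nodes)
  truth <- matrix(0L, nn, nn)
  tm <- sc$tracks$trip_matrix
  for (i in rownames(tm)) for (j in colnames(tm)) {
    if (tm[i, j] > 0)
      truth[sc$site2node[i], sc$site2node[j]] <-
        truth[sc$site2node[i], sc$site2node[j]] + tm[i, j]
  }
  truth
}

# run the pipeline stages from fixes to the extracted edge-list matrix
extracted_matrix <- function(sc, filter = TRUE) {
  fx <- if (filter) {
    filter_cascade(sc$tracks$fixes, filter_config(min_fixes_per_birdyear = 100))
  } else {
    annotate_kinematics(sc$tracks$fixes)
  }
  fx <- split_bird_years(fx)
  fx <- assign_fixes(fx, sc$nodes)
  el <- flights_to_edgelist(extract_direct_flights(fx))
  nn <- nrow(sc$nodes)
  extr <- matrix(0L, nn, nn)
  if (nrow(el)) extr[cbind(el$origin_node_id, el$dest_node_id)] <- el$weight
  extr
}
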