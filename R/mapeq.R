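# Two-level map-equation community detection on the weighted directed
# network: stationary visit rates of a teleporting random walk, the
# description-length objective, and a greedy agglomerative optimizer.

# run expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.weight_matrix <- function(network) {
  n <- nrow(network$nodes)
  W <- matrix(0, n, n, dimnames = list(network$nodes$node_id,
                                       network$nodes$node_id))
  if (nrow(network$edges))
    W[cbind(as.character(network$edges$origin_node_id),
            as.character(network$edges$dest_node_id))] <- network$edges$weight
  W
}

#' Stationary visit rates of the teleporting random walk
#'
#' Power iteration of the walk that, with probability 1 - tau, follows an
#' out-link with probability proportional to its weight (teleporting
#' uniformly from dangling nodes) and with probability tau teleports
#' uniformly.
#'
#' @param network A `spatial_network`.
#' @param tau Teleportation probability.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return Named numeric vector of visit rates summing to one.
#' @export
stationary_flow <- function(network, tau = 0.15, tol = 1e-12,
                            max_iter = 1e5) {
  n <- nrow(network$nodes)
  if (n == 1) return(stats::setNames(1, network$nodes$node_id))
  W <- .weight_matrix(network)
  s <- rowSums(W)
  dangling <- s == 0
  P <- W / ifelse(s > 0, s, 1)
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    p_new <- tau / n + (1 - tau) * (as.numeric(p %*% P) + sum(p[dangling]) / n)
    p_new <- p_new / sum(p_new)
    if (sum(abs(p_new - p)) < tol) {
      names(p_new) <- network$nodes$node_id
      return(p_new)
    }
    p <- p_new
  }
  stop("stationary flow did not converge in ", max_iter, " iterations")
}

.plogp <- function(x) {
  y <- x[x > 0]
  sum(y * log2(y))
}

#' Two-level map-equation codelength of a partition
#'
#' Expected per-step description length (bits) of the random walk under a
#' two-level Huffman coding with one index codebook over modules and one
#' codebook per module: L(M) = q H(Q) + sum_m p_m H(P_m). Module exit flows
#' include both link flow leaving the module and teleportation flow landing
#' outside it.
#'
#' @param partition Integer module assignment, one entry per node (in node
#'   order).
#' @param flow Visit rates from [stationary_flow()].
#' @param network A `spatial_network`.
#' @param tau Teleportation probability used for `flow`.
#' @return Codelength in bits.
#' @export
codelength <- function(partition, flow, network, tau = 0.15) {
  n <- nrow(network$nodes)
  stopifnot(length(partition) == n, length(flow) == n)
  mods <- sort(unique(partition))
  if (any(tabulate(match(partition, mods)) == 0)) stop("empty module")
  W <- .weight_matrix(network)
  s <- rowSums(W)
  dangling <- s == 0
  P <- W / ifelse(s > 0, s, 1)
  # flow along links u->v: (1-tau) p_u P_uv ; dangling & teleport flows are
  # uniform over all n nodes
  q <- numeric(length(mods))
  p_mod <- numeric(length(mods))
  for (k in seq_along(mods)) {
    inm <- partition == mods[k]
    n_out <- n - sum(inm)
    link_exit <- (1 - tau) * sum(flow[inm & !dangling] *
                                   rowSums(P[inm & !dangling, !inm, drop = FALSE]))
    dangle_exit <- (1 - tau) * sum(flow[inm & dangling]) * n_out / n
    tele_exit <- tau * sum(flow[inm]) * n_out / n
    q[k] <- link_exit + dangle_exit + tele_exit
    p_mod[k] <- q[k] + sum(flow[inm])
  }
  Q <- sum(q)
  index_term <- if (Q > 0) Q * (-sum((q[q > 0] / Q) * log2(q[q > 0] / Q))) else 0
  module_term <- 0
  for (k in seq_along(mods)) {
    inm <- partition == mods[k]
    pm <- p_mod[k]
    if (pm <= 0) next
    probs <- c(q[k], flow[inm]) / pm
    module_term <- module_term + pm * (-.plogp(probs)) * 1  # -sum p log p
  }
  index_term + module_term
}

#' Detect modules by greedy map-equation minimization
#'
#' Louvain-style optimization of the two-level map equation: from a seeded
#' shuffle, repeatedly move single nodes to the neighbouring module that most
#' reduces the codelength; when no move helps, greedily merge connected
#' modules; repeat from `n_restarts` shuffles and return the best partition.
#' Deterministic given `seed`.
#'
#' @param network A `spatial_network`.
#' @param seed Integer seed.
#' @param n_restarts Number of seeded restarts.
#' @param tau Teleportation probability.
#' @return A `module_partition` list: `membership` (named integer vector,
#'   modules renumbered by smallest member node id), `codelength_bits`,
#'   `n_modules`, `seed`, `tau`.
#' @export
detect_modules <- function(network, seed = 1L, n_restarts = 10, tau = 0.15) {
  n <- nrow(network$nodes)
  flow <- stationary_flow(network, tau = tau)
  W <- .weight_matrix(network)
  nbr <- lapply(seq_len(n), function(i)
    which(W[i, ] > 0 | W[, i] > 0))
  ei <- match(network$edges$origin_node_id, network$nodes$node_id)
  ej <- match(network$edges$dest_node_id, network$nodes$node_id)
  L_of <- function(part) codelength(part, flow, network, tau = tau)
  best_part <- NULL
  best_L <- Inf
  for (r in seq_len(n_restarts)) {
    ord <- .with_seed(seed + r * 1000L, sample.int(n))
    part <- seq_len(n)
    L <- L_of(part)
    repeat {
      improved <- FALSE
      for (i in ord) {
        cand <- unique(part[nbr[[i]]])
        cand <- setdiff(cand, part[i])
        for (m in cand) {
          trial <- part
          trial[i] <- m
          Lt <- L_of(trial)
          if (Lt < L - 1e-12) {
            part <- trial; L <- Lt; improved <- TRUE
          }
        }
      }
      # module-merge phase
      mods <- unique(part)
      merged <- FALSE
      if (length(mods) > 1 && length(ei)) {
        # modules connected by at least one link
        conn <- unique(cbind(pmin(part[ei], part[ej]),
                             pmax(part[ei], part[ej])))
        if (length(conn)) {
          conn <- conn[conn[, 1] != conn[, 2], , drop = FALSE]
          for (row in seq_len(nrow(conn))) {
            trial <- part
            trial[trial == conn[row, 2]] <- conn[row, 1]
            Lt <- L_of(trial)
            if (Lt < L - 1e-12) {
              part <- trial; L <- Lt; merged <- TRUE
            }
          }
        }
      }
      if (!improved && !merged) break
    }
    if (L < best_L - 1e-12) {
      best_L <- L
      best_part <- part
    }
  }
  # renumber modules by smallest member node id, in node order
  first <- tapply(seq_len(n), best_part, min)
  relabel <- match(best_part, names(sort(first)))
  membership <- stats::setNames(as.integer(relabel), network$nodes$node_id)
  structure(list(membership = membership, codelength_bits = best_L,
                 n_modules = length(unique(relabel)),
                 seed = seed, tau = tau),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition> ", x$n_modules, " modules, codelength ",
      round(x$codelength_bits, 4), " bits (tau = ", x$tau, ")\n", sep = "")
  invisible(x)
}

#' Convex hulls of module node centroids
#'
#' @param partition A `module_partition`.
#' @param network The `spatial_network` it was computed on.
#' @return Tibble with `module`, `n_nodes` and a `geometry` list column of
#'   hull rings (lon/lat), suitable for [write_geojson()].
#' @export
module_hulls <- function(partition, network) {
  memb <- partition$membership
  out <- lapply(sort(unique(memb)), function(m) {
    idx <- which(memb == m)
    xy <- cbind(network$nodes$centroid_lon[idx], network$nodes$centroid_lat[idx])
    hull <- xy[grDevices::chull(xy), , drop = FALSE]
    colnames(hull) <- c("lon", "lat")
    tibble::tibble(module = m, n_nodes = length(idx), geometry = list(list(hull)))
  })
  dplyr::bind_rows(out)
}
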