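# Valued (count) exponential random graph model with Poisson reference:
# model specification, sufficient statistics, exact dyad-factorized
# likelihood, Newton MLE with exact Fisher information, and exact simulation.
#
# Model: P(y) = [prod_{i != j} 1/y_ij!] exp(theta' g(y)) / Z(theta), with
# statistics drawn from {sum, nodeofactor(level), nodeifactor(level),
# edgecov(matrix), mutuality (negative absolute difference)}. Every such
# statistic depends on a dyad only through (y_ij, y_ji, |y_ij - y_ji|), so
# the likelihood factorizes over unordered dyads and both the MLE and
# simulation are exact (no MCMC).

#' Specify a valued ERGM
#'
#' @param terms Character vector of statistics, in coefficient order. Allowed
#'   forms: `"sum"`, `"nodeofactor:<habitat>"` (out-edges of nodes of that
#'   habitat), `"nodeifactor:<habitat>"` (in-edges), `"edgecov:<name>"`
#'   (a covariate matrix supplied in `covariates`; the distance covariate is
#'   conventionally in kilometres), `"mutuality"` (negative absolute
#'   difference of the two counts of a dyad).
#' @param habitat Character vector of node habitat labels, in node order.
#' @param covariates Named list of n-by-n numeric matrices for `edgecov`
#'   terms.
#' @return An `ergm_model` object.
#' @export
ergm_model <- function(terms, habitat, covariates = list()) {
  if (anyDuplicated(terms))
    stop("duplicate statistic in model: ",
         paste(terms[duplicated(terms)], collapse = ", "))
  n <- length(habitat)
  if (any(is.na(habitat))) stop("missing habitat for some node")
  for (tm in terms) {
    kind <- .term_kind(tm)
    if (kind %in% c("nodeofactor", "nodeifactor")) {
      lvl <- .term_arg(tm)
      if (!lvl %in% habitat)
        stop("factor level not present among node habitats: ", lvl)
    } else if (kind == "edgecov") {
      nm <- .term_arg(tm)
      mat <- covariates[[nm]]
      if (is.null(mat)) stop("missing covariate matrix: ", nm)
      if (!is.matrix(mat) || any(dim(mat) != n))
        stop("covariate matrix ", nm, " must be ", n, " x ", n)
    } else if (!kind %in% c("sum", "mutuality")) {
      stop("unsupported statistic: ", tm)
    }
  }
  structure(list(terms = terms, habitat = habitat, covariates = covariates,
                 n_nodes = n),
            class = "ergm_model")
}

.term_kind <- function(term) sub(":.*$", "", term)
.term_arg <- function(term) sub("^[^:]+:", "", term)

# count matrix (n x n, zero diagonal) from a spatial_network or a matrix
.count_matrix <- function(network, n) {
  if (is.matrix(network)) {
    stopifnot(all(dim(network) == n))
    y <- network
  } else if (inherits(network, "spatial_network")) {
    stopifnot(nrow(network$nodes) == n)
    y <- matrix(0, n, n)
    if (nrow(network$edges)) {
      io <- match(network$edges$origin_node_id, network$nodes$node_id)
      id <- match(network$edges$dest_node_id, network$nodes$node_id)
      y[cbind(io, id)] <- network$edges$weight
    }
  } else stop("network must be a spatial_network or a count matrix")
  diag(y) <- 0
  y
}

#' Sufficient statistics g(y)
#'
#' @param network A `spatial_network` or an n-by-n count matrix (node order
#'   must match the model's habitat vector).
#' @param model An [ergm_model()].
#' @return Named numeric vector, one entry per model term.
#' @export
sufficient_stats <- function(network, model) {
  n <- model$n_nodes
  y <- .count_matrix(network, n)
  g <- vapply(model$terms, function(tm) {
    kind <- .term_kind(tm)
    switch(kind,
      sum = sum(y),
      nodeofactor = sum(y[model$habitat == .term_arg(tm), , drop = FALSE]),
      nodeifactor = sum(y[, model$habitat == .term_arg(tm), drop = FALSE]),
      edgecov = sum(y * model$covariates[[.term_arg(tm)]]),
      mutuality = -sum(abs(y - t(y))) / 2
    )
  }, numeric(1))
  names(g) <- model$terms
  g
}

# Coefficient of each (non-mutuality) term on the count of the ordered pair
# (i, j): eta_ij = sum_k theta_k * c_k(i, j). Returns an n x n matrix of
# linear predictors (diagonal meaningless).
.eta_matrix <- function(theta, model) {
  n <- model$n_nodes
  eta <- matrix(0, n, n)
  for (k in seq_along(model$terms)) {
    tm <- model$terms[k]
    kind <- .term_kind(tm)
    if (kind == "sum") {
      eta <- eta + theta[k]
    } else if (kind == "nodeofactor") {
      eta <- eta + theta[k] * (model$habitat == .term_arg(tm))
    } else if (kind == "nodeifactor") {
      eta <- eta + theta[k] * rep(model$habitat == .term_arg(tm),
                                  each = n)
    } else if (kind == "edgecov") {
      eta <- eta + theta[k] * model$covariates[[.term_arg(tm)]]
    }
  }
  eta
}

.theta_mutual <- function(theta, model) {
  k <- which(model$terms == "mutuality")
  if (length(k)) theta[k] else 0
}

#' Linear predictor of an ordered pair
#'
#' eta_ij = theta_sum + theta_of(habitat_i) + theta_if(habitat_j) +
#' sum over edge covariates of theta_cov * x_ij. The mutuality coefficient is
#' not part of the linear predictor (it couples the two counts of a dyad).
#'
#' @param i,j Node indices (in model node order).
#' @param theta Coefficient vector aligned with the model terms.
#' @param model An [ergm_model()].
#' @return Scalar linear predictor.
#' @export
dyad_linear_predictor <- function(i, j, theta, model) {
  stopifnot(length(theta) == length(model$terms))
  .eta_matrix(theta, model)[i, j]
}

#' Log partition function of one dyad
#'
#' log Z_ij = log sum over (a, b >= 0) of
#' exp(a eta_ij + b eta_ji - theta_mutual |a - b|) / (a! b!), evaluated by
#' adaptively truncated summation in log space; the truncation cap guarantees
#' a relative tail mass below `tolerance`.
#'
#' @param eta_ij,eta_ji Linear predictors of the two ordered pairs.
#' @param theta_mutual Mutuality coefficient (0 if absent).
#' @param tolerance Relative tail-mass bound.
#' @return List with `logZ` and `cap` (the truncation caps used).
#' @export
dyad_log_partition <- function(eta_ij, eta_ji, theta_mutual = 0,
                               tolerance = 1e-10) {
  m <- dyad_moments_cpp(eta_ij, eta_ji, theta_mutual, tolerance)
  list(logZ = m$logZ[1], cap = c(a = m$cap_a[1], b = m$cap_b[1]))
}

# Per-dyad machinery shared by likelihood, Fisher information and simulation.
# Unordered dyads are enumerated as i < j with a = y_ij (ordered pair i->j)
# and b = y_ji. The mapping matrix M (p x 3) of each dyad carries the
# coefficients of its statistics on (a, b, |a-b|).
.dyad_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

.dyad_maps <- function(model) {
  n <- model$n_nodes
  idx <- .dyad_index(n)
  p <- length(model$terms)
  nd <- nrow(idx)
  Ma <- matrix(0, nd, p); Mb <- matrix(0, nd, p); Md <- matrix(0, nd, p)
  for (k in seq_len(p)) {
    tm <- model$terms[k]
    kind <- .term_kind(tm)
    if (kind == "sum") {
      Ma[, k] <- 1; Mb[, k] <- 1
    } else if (kind == "nodeofactor") {
      inl <- model$habitat == .term_arg(tm)
      Ma[, k] <- inl[idx[, 1]]; Mb[, k] <- inl[idx[, 2]]
    } else if (kind == "nodeifactor") {
      inl <- model$habitat == .term_arg(tm)
      Ma[, k] <- inl[idx[, 2]]; Mb[, k] <- inl[idx[, 1]]
    } else if (kind == "edgecov") {
      X <- model$covariates[[.term_arg(tm)]]
      Ma[, k] <- X[idx]; Mb[, k] <- X[idx[, c(2, 1)]]
    } else if (kind == "mutuality") {
      Md[, k] <- -1
    }
  }
  list(idx = idx, Ma = Ma, Mb = Mb, Md = Md)
}

.dyad_etas <- function(theta, model, maps) {
  eta <- .eta_matrix(theta, model)
  list(e1 = eta[maps$idx], e2 = eta[maps$idx[, c(2, 1)]])
}

#' Log-likelihood and gradient
#'
#' l(theta) = theta' g(y) - sum over dyads of log Z_ij(theta) - sum over
#' ordered pairs of log y_ij!; the gradient is g(y) minus the expected
#' statistics under theta, assembled from exact truncated per-dyad moments.
#'
#' @param theta Coefficient vector.
#' @param network A `spatial_network` or count matrix.
#' @param model An [ergm_model()].
#' @param tolerance Dyad truncation tolerance.
#' @return List with `loglik`, `gradient`, and `fisher` (the exact Fisher
#'   information, i.e. minus the Hessian).
#' @export
loglik_and_gradient <- function(theta, network, model, tolerance = 1e-10) {
  stopifnot(length(theta) == length(model$terms))
  n <- model$n_nodes
  y <- .count_matrix(network, n)
  maps <- .dyad_maps(model)
  et <- .dyad_etas(theta, model, maps)
  thm <- .theta_mutual(theta, model)
  mom <- dyad_moments_cpp(et$e1, et$e2, thm, tolerance)
  g_obs <- sufficient_stats(y, model)
  ll <- sum(theta * g_obs) - sum(mom$logZ) - sum(lgamma(y + 1)) + sum(lgamma(diag(y) + 1))
  # E[g] = sum_d (Ma ea + Mb eb + Md ed)
  eg <- colSums(maps$Ma * mom$ea) + colSums(maps$Mb * mom$eb) +
    colSums(maps$Md * mom$ed)
  grad <- g_obs - eg
  # Fisher info: sum_d M Cov3 M' with M = [Ma | Mb | Md] columns (a, b, d)
  p <- length(theta)
  fisher <- matrix(0, p, p)
  for (r in seq_len(p)) for (s in r:p) {
    v <- sum(maps$Ma[, r] * maps$Ma[, s] * mom$vaa +
             maps$Mb[, r] * maps$Mb[, s] * mom$vbb +
             maps$Md[, r] * maps$Md[, s] * mom$vdd +
             (maps$Ma[, r] * maps$Mb[, s] + maps$Mb[, r] * maps$Ma[, s]) * mom$vab +
             (maps$Ma[, r] * maps$Md[, s] + maps$Md[, r] * maps$Ma[, s]) * mom$vad +
             (maps$Mb[, r] * maps$Md[, s] + maps$Md[, r] * maps$Mb[, s]) * mom$vbd)
    fisher[r, s] <- v; fisher[s, r] <- v
  }
  list(loglik = ll, gradient = grad, fisher = fisher)
}

#' Fit the valued ERGM by exact maximum likelihood
#'
#' Newton iterations with step halving on the exact dyad-factorized
#' likelihood; standard errors from the inverse Fisher information at the
#' optimum; z = estimate/SE with two-sided normal p values.
#'
#' @param network A `spatial_network` or count matrix.
#' @param model An [ergm_model()].
#' @param init Starting coefficients (default all zero).
#' @param max_iter Newton iteration cap.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param tolerance Dyad truncation tolerance.
#' @return An `ergm_fit`: tibble `coefficients` (term, estimate, se, z,
#'   p_value) plus `loglik`, `converged`, `iterations`.
#' @export
fit_mle <- function(network, model, init = NULL, max_iter = 60, tol = 1e-8,
                    tolerance = 1e-10) {
  p <- length(model$terms)
  theta <- if (is.null(init)) numeric(p) else init
  stopifnot(length(theta) == p)
  ev <- loglik_and_gradient(theta, network, model, tolerance)
  # identifiability check at the start
  qr_f <- qr(ev$fisher)
  if (qr_f$rank < p) {
    bad <- model$terms[qr_f$pivot[(qr_f$rank + 1):p]]
    stop("model not identifiable; collinear statistic(s): ",
         paste(bad, collapse = ", "))
  }
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    if (max(abs(ev$gradient)) < tol * max(1, abs(ev$loglik))) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(ev$fisher, ev$gradient), error = function(e) NULL)
    if (is.null(step)) step <- ev$gradient / max(diag(ev$fisher))
    # step halving: accept the first step that improves the log-likelihood
    accepted <- FALSE
    for (h in 0:30) {
      cand <- theta + step / 2^h
      ev_c <- tryCatch(loglik_and_gradient(cand, network, model, tolerance),
                       error = function(e) NULL)
      if (!is.null(ev_c) && is.finite(ev_c$loglik) &&
          ev_c$loglik >= ev$loglik - 1e-12) {
        theta <- cand; ev <- ev_c; accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  if (!converged && max(abs(ev$gradient)) < 1e-4 * max(1, abs(ev$loglik)))
    converged <- TRUE
  if (!converged)
    warning("fit_mle did not fully converge after ", it, " iterations ",
            "(max |gradient| = ", signif(max(abs(ev$gradient)), 3), ")")
  vcov <- solve(ev$fisher)
  se <- sqrt(pmax(diag(vcov), 0))
  z <- theta / se
  coef_tab <- tibble::tibble(
    term = model$terms,
    estimate = as.numeric(theta),
    se = as.numeric(se),
    z = as.numeric(z),
    p_value = 2 * stats::pnorm(-abs(z))
  )
  structure(list(coefficients = coef_tab, loglik = ev$loglik,
                 vcov = vcov, converged = converged, iterations = it,
                 model = model),
            class = "ergm_fit")
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat("Valued ERGM (Poisson reference), exact dyad-factorized MLE\n")
  cat("log-likelihood:", format(x$loglik, digits = 8),
      if (x$converged) " (converged)" else " (NOT converged)", "\n\n")
  tab <- x$coefficients
  stars <- cut(tab$p_value, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  out <- data.frame(
    Term = tab$term,
    Estimate = sprintf("% .2f", tab$estimate),
    SE = sprintf("%.2f", tab$se),
    `z value` = sprintf("% .2f", tab$z),
    `p value` = ifelse(tab$p_value < 0.001, "< 0.001",
                       sprintf("%.3f", tab$p_value)),
    ` ` = as.character(stars),
    check.names = FALSE)
  print(out, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Simulate a network from the model
#'
#' Exact sampling: for each unordered dyad the truncated joint pmf of
#' (y_ij, y_ji) is enumerated and one draw is taken by inverse CDF;
#' dyads are independent. Reproducible given `seed`.
#'
#' @param theta Coefficient vector.
#' @param model An [ergm_model()].
#' @param seed Integer seed.
#' @param nodes Optional site-node tibble for the returned network; defaults
#'   to a minimal node table built from the model's habitat vector.
#' @param tolerance Dyad truncation tolerance.
#' @return A `spatial_network` whose edges carry the simulated counts.
#' @export
simulate_network <- function(theta, model, seed = 1L, nodes = NULL,
                             tolerance = 1e-10) {
  n <- model$n_nodes
  maps <- .dyad_maps(model)
  et <- .dyad_etas(theta, model, maps)
  thm <- .theta_mutual(theta, model)
  u <- .with_seed(seed, stats::runif(nrow(maps$idx)))
  ab <- dyad_sample_cpp(et$e1, et$e2, thm, tolerance, u)
  y <- matrix(0L, n, n)
  y[maps$idx] <- ab[, 1]
  y[maps$idx[, c(2, 1)]] <- ab[, 2]
  if (is.null(nodes)) {
    nodes <- tibble::tibble(node_id = seq_len(n), habitat = model$habitat,
                            centroid_lon = NA_real_, centroid_lat = NA_real_)
  }
  nz <- which(y > 0, arr.ind = TRUE)
  edges <- tibble::tibble(origin_node_id = nodes$node_id[nz[, 1]],
                          dest_node_id = nodes$node_id[nz[, 2]],
                          weight = y[nz])
  edges <- dplyr::arrange(edges, .data$origin_node_id, .data$dest_node_id)
  dist_m <- if (!is.null(model$covariates$distance_km)) {
    model$covariates$distance_km * 1000
  } else matrix(0, n, n)
  dimnames(dist_m) <- list(nodes$node_id, nodes$node_id)
  structure(list(nodes = nodes, edges = edges, distance_m = dist_m),
            class = "spatial_network")
}

#' Multiplicative interpretation of a coefficient
#'
#' Poisson-reference coefficients act log-linearly on expected counts:
#' a coefficient theta multiplies the expected number of direct flights by
#' exp(theta) per unit of its statistic.
#'
#' @param coef A single coefficient.
#' @return List with `multiplier` (exp(coef), full precision) and
#'   `interpretation` (text with the multiplier to 3 significant figures).
#' @export
coefficient_multiplier <- function(coef) {
  stopifnot(is.finite(coef))
  mult <- exp(coef)
  list(multiplier = mult,
       interpretation = sprintf(
         "expected direct flights multiplied by exp(%.3g) = %.3g per unit of the statistic",
         coef, mult))
}
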