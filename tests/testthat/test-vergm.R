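test_that("sufficient statistics match hand arithmetic and a brute-force loop", {
  hab <- c("Landfills", "Marshes")
  d <- matrix(c(0, 2, 2, 0), 2, 2)
  m <- ergm_model(c("sum", "nodeofactor:Landfills", "nodeifactor:Marshes",
                    "edgecov:distance_km", "mutuality"),
                  hab, covariates = list(distance_km = d))
  y <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE)  # y[1,2]=3, y[2,1]=1
  g <- sufficient_stats(y, m)
  expect_equal(unname(g), c(4, 3, 3, 8, -2))
  # empty network: all statistics zero
  expect_equal(unname(sufficient_stats(matrix(0, 2, 2), m)), rep(0, 5))
  # random 5-node networks against the double-loop oracle
  set.seed(31)
  for (rep in 1:5) {
    hab <- sample(c("Landfills", "Marshes", "Rice fields"), 5, replace = TRUE)
    hab[1] <- "Landfills"; hab[2] <- "Marshes"; hab[3] <- "Rice fields"
    D <- matrix(runif(25, 1, 50), 5, 5); D <- (D + t(D)) / 2; diag(D) <- 0
    terms <- c("sum", "nodeofactor:Landfills", "nodeifactor:Marshes",
               "nodeifactor:Rice fields", "edgecov:distance_km", "mutuality")
    m <- ergm_model(terms, hab, covariates = list(distance_km = D))
    y <- matrix(rpois(25, 2), 5, 5); diag(y) <- 0
    expect_equal(unname(sufficient_stats(y, m)),
                 brute_stats(y, hab, terms, list(distance_km = D)))
  }
})

test_that("the mutuality statistic is nonpositive and zero iff reciprocal", {
  hab <- rep("Landfills", 4)
  m <- ergm_model(c("sum", "mutuality"), hab)
  set.seed(2)
  for (rep in 1:20) {
    y <- matrix(rpois(16, 2), 4, 4); diag(y) <- 0
    g <- sufficient_stats(y, m)
    expect_lte(g[["mutuality"]], 0)
    if (all(y == t(y))) expect_equal(g[["mutuality"]], 0)
  }
  y <- matrix(c(0, 2, 2, 0), 2, 2)
  m2 <- ergm_model("mutuality", rep("Landfills", 2))
  expect_equal(unname(sufficient_stats(y, m2)), 0)
})

test_that("linear predictors compose additively", {
  hab <- c("Landfills", "Marshes")
  D <- matrix(c(0, 10, 10, 0), 2, 2)
  m <- ergm_model(c("sum", "nodeofactor:Landfills", "edgecov:distance_km"),
                  hab, covariates = list(distance_km = D))
  expect_equal(dyad_linear_predictor(1, 2, c(0, 0, 0), m), 0)
  # intercept plus the landfill out-factor
  expect_equal(dyad_linear_predictor(1, 2, c(4.75, 1.49, 0), m), 6.24)
  # 10 km at -0.15 per km lowers the predictor by 1.5
  expect_equal(dyad_linear_predictor(1, 2, c(4.75, 1.49, -0.15), m),
               6.24 - 1.5)
  # the receiving node's out-factor does not apply
  expect_equal(dyad_linear_predictor(2, 1, c(4.75, 1.49, 0), m), 4.75)
})

test_that("dyad log partition matches closed forms and a high-cap oracle", {
  # independent unit Poissons: Z = e * e
  expect_equal(dyad_log_partition(0, 0, 0)$logZ, 2, tolerance = 1e-12)
  # no mutuality: log Z = e^eta1 + e^eta2
  for (e1 in c(-1, 0.5, 2)) for (e2 in c(-0.5, 1.5))
    expect_equal(dyad_log_partition(e1, e2, 0)$logZ, exp(e1) + exp(e2),
                 tolerance = 1e-10)
  # with mutuality coupling: brute-force double sum to cap 200
  expect_equal(dyad_log_partition(0.5, 0.5, 0.3)$logZ,
               brute_log_partition(0.5, 0.5, 0.3), tolerance = 1e-10)
  expect_equal(dyad_log_partition(1.2, -0.4, 0.85)$logZ,
               brute_log_partition(1.2, -0.4, 0.85), tolerance = 1e-10)
  expect_equal(dyad_log_partition(2, 1, -0.5)$logZ,
               brute_log_partition(2, 1, -0.5), tolerance = 1e-10)
})

test_that("log-likelihood and gradient agree with direct evaluation", {
  hab <- c("Landfills", "Marshes")
  m <- ergm_model("sum", hab)
  # empty 2-node network at theta = 0: one dyad contributes -log Z = -2
  ev <- loglik_and_gradient(0, matrix(0, 2, 2), m)
  expect_equal(ev$loglik, -2)
  # gradient against central finite differences on a 4-node model
  set.seed(12)
  hab4 <- c("Landfills", "Marshes", "Rice fields", "Marshes")
  D <- matrix(runif(16, 1, 30), 4, 4); D <- (D + t(D)) / 2; diag(D) <- 0
  m4 <- ergm_model(c("sum", "nodeofactor:Landfills", "nodeifactor:Marshes",
                     "edgecov:distance_km", "mutuality"),
                   hab4, covariates = list(distance_km = D))
  y <- matrix(rpois(16, 2), 4, 4); diag(y) <- 0
  theta <- c(0.3, 0.2, -0.1, -0.02, 0.15)
  ev <- loglik_and_gradient(theta, y, m4)
  h <- 1e-6
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm_ <- theta; tm_[k] <- tm_[k] - h
    fd <- (loglik_and_gradient(tp, y, m4)$loglik -
           loglik_and_gradient(tm_, y, m4)$loglik) / (2 * h)
    expect_equal(ev$gradient[[k]], fd, tolerance = 1e-5)
  }
  # the Fisher information matches minus the Hessian of the log-likelihood
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm_ <- theta; tm_[k] <- tm_[k] - h
    fdg <- (loglik_and_gradient(tp, y, m4)$gradient -
            loglik_and_gradient(tm_, y, m4)$gradient) / (2 * h)
    expect_equal(ev$fisher[k, ], -unname(fdg), tolerance = 1e-4)
  }
})

test_that("likelihood is concave along random line sections", {
  set.seed(77)
  hab <- c("Landfills", "Marshes", "Rice fields", "Marshes")
  m <- ergm_model(c("sum", "nodeofactor:Landfills", "mutuality"), hab)
  y <- matrix(rpois(16, 2), 4, 4); diag(y) <- 0
  for (rep in 1:5) {
    a <- rnorm(3, sd = 0.3); b <- rnorm(3, sd = 0.3)
    t_grid <- seq(-1, 1, length.out = 9)
    ll <- vapply(t_grid, function(t)
      loglik_and_gradient(a + t * b, y, m)$loglik, numeric(1))
    expect_true(all(diff(diff(ll)) <= 1e-8))
  }
})

test_that("the sum-only MLE is the log mean count, and misuse errors early", {
  set.seed(9)
  y <- matrix(rpois(36, 3), 6, 6); diag(y) <- 0
  m <- ergm_model("sum", rep("Landfills", 6))
  fit <- fit_mle(y, m)
  expect_equal(fit$coefficients$estimate, log(mean(y[row(y) != col(y)])),
               tolerance = 1e-7)
  # gradient vanishes at the optimum
  ev <- loglik_and_gradient(fit$coefficients$estimate, y, m)
  expect_lt(max(abs(ev$gradient)), 1e-5)
  # duplicate statistics are rejected
  expect_error(ergm_model(c("sum", "sum"), rep("Landfills", 2)), "duplicate")
  # unknown factor level rejected
  expect_error(ergm_model("nodeofactor:Castle", c("Landfills", "Marshes")),
               "Castle")
  # collinear statistics are named
  D <- matrix(1, 4, 4); diag(D) <- 0
  mm <- ergm_model(c("sum", "edgecov:distance_km"), rep("Landfills", 4),
                   covariates = list(distance_km = D))
  expect_error(fit_mle(matrix(rpois(16, 2), 4, 4), mm), "identifiable")
})

test_that("fits recover generating coefficients on a small model", {
  hab <- rep(c("Landfills", "Marshes"), c(6, 10))
  D <- .with_seed(5, {
    d <- matrix(0, 16, 16)
    d[upper.tri(d)] <- runif(120, 2, 60)
    d + t(d)
  })
  terms <- c("sum", "nodeofactor:Landfills", "edgecov:distance_km",
             "mutuality")
  theta <- c(2.5, 0.8, -0.08, 0.4)
  m <- ergm_model(terms, hab, covariates = list(distance_km = D))
  est <- sapply(1:8, function(i)
    fit_mle(simulate_network(theta, m, seed = i), m)$coefficients$estimate)
  mu <- rowMeans(est)
  se <- apply(est, 1, stats::sd) / sqrt(ncol(est))
  expect_true(all(abs(mu - theta) <= pmax(3 * se, 0.02)))
  # reported z equals estimate over SE
  fit <- fit_mle(simulate_network(theta, m, seed = 1), m)
  expect_equal(fit$coefficients$z,
               fit$coefficients$estimate / fit$coefficients$se)
  expect_true(all(fit$coefficients$se > 0))
})

test_that("exact simulation is reproducible and has the right marginals", {
  # theta_mutual = 0: counts are independent Poisson(e^eta) per ordered pair
  hab <- rep("Landfills", 45)
  m <- ergm_model("sum", hab)
  net1 <- simulate_network(log(2), m, seed = 3)
  net2 <- simulate_network(log(2), m, seed = 3)
  expect_identical(net1$edges, net2$edges)
  y <- .count_matrix(net1, 45)
  counts <- y[row(y) != col(y)]       # 1980 ordered pairs
  expect_equal(mean(counts), 2, tolerance = 0.075)
  # chi-square goodness of fit against Poisson(2), alpha = 0.01
  brk <- c(0:5, Inf)
  obs <- table(cut(counts, breaks = c(-0.5, 0.5 + 0:4, Inf)))
  pr <- c(dpois(0:4, 2), 1 - ppois(4, 2))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
  # positive mutuality coefficient penalizes asymmetry
  mm <- ergm_model(c("sum", "mutuality"), rep("Landfills", 30))
  y0 <- .count_matrix(simulate_network(c(log(2), 0), mm, seed = 11), 30)
  y1 <- .count_matrix(simulate_network(c(log(2), 1.2), mm, seed = 11), 30)
  asym <- function(y) mean(abs(y - t(y))[upper.tri(y)])
  expect_lt(asym(y1), asym(y0))
})

test_that("coefficient multipliers reproduce the log-linear interpretation", {
  expect_equal(coefficient_multiplier(0)$multiplier, 1)
  expect_equal(coefficient_multiplier(4.75)$multiplier, exp(4.75))
  expect_equal(coefficient_multiplier(4.75)$multiplier, 115.58, tolerance = 1e-4)
  expect_equal(coefficient_multiplier(1.49)$multiplier, 4.437, tolerance = 1e-3)
  expect_match(coefficient_multiplier(1.49)$interpretation, "4.44")
})
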