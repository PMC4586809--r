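test_that("linear predictor assembles the log relative risk", {
  g <- path_graph(3L)
  st <- parameter_state(alpha = 0, delta0 = 0, beta = numeric(0),
                        u = numeric(3L), v = numeric(3L), t = numeric(2L),
                        psi = matrix(0, 3L, 2L),
                        tau = list(u = 1, v = 1, t = 1, psi = 1))
  cells <- data.frame(area = c(1L, 2L), year = c(1L, 2L), eth = c(1L, 0L))
  expect_equal(linear_predictor(st, cells), c(0, 0))

  st$alpha <- 0.1; st$delta0 <- 0.05
  expect_equal(linear_predictor(st, cells), c(0.15, 0.1))

  # reference group never receives the disparity term
  st$delta <- c(0.5, -0.2, -0.3)
  eta <- linear_predictor(st, data.frame(area = 2L, year = 1L, eth = 0L))
  expect_equal(eta, 0.1)

  expect_error(linear_predictor(st, data.frame(area = 9L, year = 1L,
                                               eth = 0L)), "out of range")
})

test_that("poisson_loglik matches the closed form", {
  expect_equal(poisson_loglik(0L, 1), -1)
  expect_equal(poisson_loglik(1L, 1), -1)
  expect_equal(poisson_loglik(2L, 2), log(2) - 2)
  expect_equal(poisson_loglik(c(0L, 5L), c(1, 2)),
               dpois(c(0L, 5L), c(1, 2), log = TRUE))
  expect_error(poisson_loglik(1L, 0), "positive")
})

test_that("ICAR log density is the pairwise-difference quadratic form", {
  g2 <- adjacency_graph(rbind(c("A001", "A002")))
  expect_equal(icar_logdensity(c(5, 5), 3, g2), 0)
  expect_equal(icar_logdensity(c(0, 1), 2, g2), -1)
  g3 <- path_graph(3L)
  expect_equal(icar_logdensity(c(0, 1, 3), 1, g3), -2.5)
  expect_error(icar_logdensity(c(0, 1), 1, g3), "match graph")
  expect_error(icar_logdensity(c(0, 1, 3), -1, g3), "positive")
  # islands contribute nothing
  giso <- adjacency_graph(rbind(c("A001", "A002")),
                          areas = c("A001", "A002", "A003"))
  expect_equal(icar_logdensity(c(0, 1, 100), 2, giso), -1)
})

test_that("ICAR equals the degenerate Gaussian form tau*(D - W) exactly", {
  set.seed(42)
  for (n in c(3L, 5L, 6L)) {
    g <- make_graph(n, "grid")
    D <- diag(g$n, n)
    W <- matrix(0, n, n)
    W[g$edges] <- 1; W[g$edges[, 2:1, drop = FALSE]] <- 1
    Q <- D - W
    for (r in 1:20) {
      x <- rnorm(n)
      expect_equal(icar_logdensity(x, 1.7, g),
                   -(1.7 / 2) * drop(t(x) %*% Q %*% x), tolerance = 1e-12)
    }
  }
})

test_that("implied ICAR full conditional is N(neighbour mean, 1/(tau*n_i))", {
  g <- make_graph(6L, "grid")
  set.seed(9)
  x <- rnorm(6L)
  tau <- 2.5
  for (i in seq_len(6L)) {
    m <- mean(x[g$nb[[i]]])
    # the log density as a function of x_i is quadratic; read off its
    # coefficients from three evaluations
    f <- vapply(c(-1, 0, 1), function(xi) {
      xx <- x; xx[i] <- xi
      icar_logdensity(xx, tau, g)
    }, 0)
    a2 <- (f[1L] + f[3L] - 2 * f[2L]) / 2      # coefficient of x_i^2
    a1 <- (f[3L] - f[1L]) / 2                  # coefficient of x_i
    expect_equal(a2, -tau * g$n[i] / 2)
    expect_equal(-a1 / (2 * a2), m)            # conditional mean
  }
})

test_that("iid normal and gamma priors follow the stated forms", {
  expect_equal(iid_normal_logprior(0, 7), 0.5 * log(7) - 0.5 * log(2 * pi))
  x <- c(0, 0, 0, 0)
  expect_equal(iid_normal_logprior(x, 2) - iid_normal_logprior(x, 1),
               (4 / 2) * log(2))
  expect_error(iid_normal_logprior(1, 0), "positive")

  expect_equal(gamma_logprior(1000),
               dgamma(1000, 0.5, rate = 5e-4, log = TRUE))
  dens_mass <- stats::integrate(function(t) exp(gamma_logprior(t)),
                                0, Inf, rel.tol = 1e-9)$value
  expect_equal(dens_mass, 1, tolerance = 1e-6)
  expect_error(gamma_logprior(-1), "positive")
})

test_that("log posterior decomposes into likelihood plus priors", {
  fx <- small_sim(seed = 4L, n_areas = 9L, n_years = 2L)
  g <- fx$graph
  spec <- model_spec(3)
  st <- random_state(g, J = 2L, p = 4L, model = 3L, seed = 2L)
  lp <- log_posterior(st, fx$panel, fx$expected, g, spec)
  ll <- log_posterior(st, fx$panel, fx$expected, g, spec,
                      likelihood_only = TRUE)
  priors <- iid_normal_logprior(st$delta0, spec$fixed_prec) +
    iid_normal_logprior(st$beta, spec$fixed_prec) +
    icar_logdensity(st$u, st$tau$u, g) +
    iid_normal_logprior(st$v, st$tau$v) +
    iid_normal_logprior(st$t, st$tau$t) +
    iid_normal_logprior(as.vector(st$psi), st$tau$psi) +
    icar_logdensity(st$delta, st$tau$delta, g) +
    sum(gamma_logprior(unlist(st$tau)))
  expect_equal(lp, ll + priors, tolerance = 1e-10)
})

test_that("vectorized likelihood equals a naive per-cell loop", {
  fx <- small_sim(seed = 5L, n_areas = 9L, n_years = 2L)
  st <- random_state(fx$graph, J = 2L, p = 4L, model = 3L, seed = 3L)
  ll <- log_posterior(st, fx$panel, fx$expected, fx$graph, model_spec(3),
                      likelihood_only = TRUE)
  # naive loop over panel rows
  covs <- attr(fx$panel, "covariates")
  Xr <- as.matrix(covs[-1L])
  X <- scale(Xr)
  areas <- attr(fx$panel, "areas"); years <- attr(fx$panel, "years")
  acc <- 0
  for (r in seq_len(nrow(fx$panel))) {
    e <- fx$expected$expected[r]
    if (e <= 0) next
    i <- match(fx$panel$area_id[r], areas)
    j <- match(fx$panel$year[r], years)
    eth <- fx$panel$group[r]
    eta <- st$alpha + (st$delta0 + st$delta[i]) * eth +
      sum(X[i, ] * st$beta) + st$u[i] + st$v[i] + st$t[j] + st$psi[i, j]
    mu <- e * exp(eta)
    acc <- acc - mu + fx$panel$count[r] * log(mu) -
      lgamma(fx$panel$count[r] + 1)
  }
  expect_equal(ll, acc, tolerance = 1e-10)
})

test_that("Model 2 collapses to Model 1 when deviations vanish", {
  fx <- small_sim(seed = 6L, n_areas = 9L, n_years = 2L)
  st1 <- random_state(fx$graph, J = 2L, p = 4L, model = 1L, seed = 4L)
  st2 <- st1
  st2$delta <- numeric(9L)
  st2$tau$delta <- 16
  lp1 <- log_posterior(st1, fx$panel, fx$expected, fx$graph, model_spec(1))
  lp2 <- log_posterior(st2, fx$panel, fx$expected, fx$graph, model_spec(2))
  extra <- iid_normal_logprior(numeric(9L), 16) + gamma_logprior(16)
  expect_equal(lp2, lp1 + extra, tolerance = 1e-10)
})

test_that("model_spec validates and round-trips through YAML", {
  expect_error(model_spec(4), "model must be")
  expect_error(model_spec(1, fixed_prec = -1))
  sp <- model_spec(2, tau_prior = "flat", tau_upper = 5e4, threshold = 1.5)
  back <- spec_from_yaml(spec_to_yaml(sp))
  expect_equal(back, sp)
})
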