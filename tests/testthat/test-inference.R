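# A minimal hand-built fit object for testing post-processing functions
# without running the sampler.
fake_fit <- function(eta_draws, cells, areas, delta0, delta = NULL,
                     model = 2L) {
  K <- length(delta0)
  structure(list(
    draws = list(alpha = numeric(K), delta0 = delta0,
                 beta = matrix(numeric(0), K, 0L), delta = delta,
                 tau = matrix(1, K, 1L, dimnames = list(NULL, "tau_u"))),
    eta_draws = eta_draws, eta_mean = colMeans(eta_draws),
    theta_mean = colMeans(exp(eta_draws)),
    deviance = apply(eta_draws, 1L, function(eta)
      -2 * sum(poisson_loglik(cells$count, cells$expected * exp(eta)))),
    chain = rep(1L, K), cells = cells, spec = model_spec(model),
    components = "disparity", areas = areas, n_draws = K,
    fingerprint = "x"), class = "disparity_fit")
}

test_that("summarize_draws gives equal-tailed intervals containing the mean", {
  expect_equal(summarize_draws(rep(3, 10)), c(mean = 3, lo95 = 3, hi95 = 3))
  s <- summarize_draws(1:1000)
  expect_equal(unname(s["mean"]), 500.5)
  set.seed(1)
  z <- rnorm(10000)
  s2 <- summarize_draws(z)
  expect_equal(unname(s2["lo95"]), -1.96, tolerance = 0.08 / 1.96)
  expect_equal(unname(s2["hi95"]), 1.96, tolerance = 0.08 / 1.96)
  expect_true(s2["lo95"] <= s2["mean"] && s2["mean"] <= s2["hi95"])
  expect_error(summarize_draws(numeric(1L)), "at least 2")
})

test_that("disparity_percent is the exponential excess-risk transform", {
  expect_equal(disparity_percent(0), 0)
  expect_equal(disparity_percent(log(2)), 100)
  expect_equal(round(disparity_percent(0.052), 1), 5.3)
  expect_equal(round(disparity_percent(0.152), 1), 16.4)
})

test_that("identical seeds give identical fits", {
  fx <- small_sim(seed = 10L, n_areas = 16L, n_years = 2L)
  cfg <- mcmc_config(chains = 2L, iterations = 200L, burnin = 100L,
                     thin = 2L, seed = 77L)
  f1 <- fit_model(model_spec(2), fx$panel, fx$expected, fx$graph, cfg)
  f2 <- fit_model(model_spec(2), fx$panel, fx$expected, fx$graph, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$summary, f2$summary)
  expect_equal(f1$n_draws, 2L * (200L - 100L) %/% 2L)
})

test_that("intercept-only fit matches the conjugate log-Gamma posterior", {
  # y ~ Poisson(e * exp(alpha)), flat prior on alpha: the posterior of
  # exp(alpha) is Gamma(sum(y), sum(e)), so E[alpha] = digamma(sum y) -
  # log(sum e).
  set.seed(21)
  df <- data.frame(area_id = sprintf("A%02d", 1:10),
                   year = rep(0:1, each = 10L), group = rep(0:1, 10L),
                   cancer = "x", count = rpois(20L, 5), population = 1000)
  pan <- areal_panel(df, complete = TRUE)
  e <- expected_counts(pan, data.frame(cancer = "x", group = 0:1,
                                       rate = 0.005))
  g <- make_graph(length(attr(pan, "areas")), "grid")
  g$areas <- attr(pan, "areas")
  cfg <- mcmc_config(chains = 1L, iterations = 3000L, burnin = 500L,
                     thin = 1L, seed = 3L)
  fit <- fit_model(model_spec(1), pan, e, g, cfg, components = "none")
  sy <- sum(fit$cells$count); se <- sum(fit$cells$expected)
  exact_mean <- digamma(sy) - log(se)
  mc_se <- stats::sd(fit$draws$alpha) / sqrt(arealdisp:::ess(fit$draws$alpha))
  expect_lt(abs(mean(fit$draws$alpha) - exact_mean), 3 * mc_se)
  # the full posterior shape matches too (variance of log-Gamma = psi'(sy))
  expect_equal(stats::var(fit$draws$alpha), trigamma(sy), tolerance = 0.15)
})

test_that("fitted_sir: identity at zero, monotone in alpha, Jensen gap", {
  cells <- data.frame(area_id = c("A", "B"), year = 0L, group = 0:1,
                      count = c(2L, 3L), expected = c(2, 3))
  eta0 <- matrix(0, 50L, 2L)
  f0 <- fake_fit(eta0, cells, c("A", "B"), delta0 = numeric(50L))
  fs0 <- fitted_sir(f0)
  expect_equal(fs0$mean, c(1, 1))
  expect_equal(fs0$lo95, c(1, 1))

  set.seed(5)
  eta <- matrix(rnorm(100L, 0, 0.5), 50L, 2L)
  f1 <- fake_fit(eta, cells, c("A", "B"), delta0 = numeric(50L))
  f2 <- fake_fit(eta + 0.1, cells, c("A", "B"), delta0 = numeric(50L))
  expect_equal(fitted_sir(f2)$mean, fitted_sir(f1)$mean * exp(0.1))
  # posterior mean of exp exceeds exp of posterior mean on non-degenerate draws
  expect_true(all(fitted_sir(f1)$mean > exp(colMeans(eta))))
})

test_that("disparity_surface transforms delta draws per area", {
  cells <- data.frame(area_id = "A", year = 0L, group = 1L, count = 1L,
                      expected = 1)
  K <- 40L
  # constant delta0 = 0.1, zero deviations -> surface exp(0.1) everywhere
  f <- fake_fit(matrix(0, K, 1L), cells, c("A", "B"),
                delta0 = rep(0.1, K), delta = matrix(0, K, 2L))
  surf <- disparity_surface(f)
  expect_equal(surf$mean, rep(exp(0.1), 2L), tolerance = 1e-12)
  expect_equal(surf$lo95, surf$hi95)

  # all-zero draws -> surface of exact ones
  f0 <- fake_fit(matrix(0, K, 1L), cells, c("A", "B"),
                 delta0 = numeric(K), delta = matrix(0, K, 2L))
  expect_equal(disparity_surface(f0)$mean, c(1, 1))

  # non-degenerate draws: mean of exp differs from exp of mean (Jensen)
  set.seed(8)
  fd <- fake_fit(matrix(0, K, 1L), cells, c("A", "B"),
                 delta0 = rnorm(K, 0.1, 0.2), delta = matrix(0, K, 2L))
  expect_gt(disparity_surface(fd)$mean[1L], exp(0.1 - 0.05))
  expect_false(isTRUE(all.equal(disparity_surface(fd)$mean[1L],
                                exp(mean(fd$draws$delta0)))))
})

test_that("constrained blocks satisfy sum-to-zero in every retained draw", {
  fx <- small_sim(seed = 12L, n_areas = 16L, n_years = 3L)
  cfg <- mcmc_config(chains = 1L, iterations = 300L, burnin = 100L,
                     thin = 2L, seed = 9L)
  fit <- fit_model(model_spec(3), fx$panel, fx$expected, fx$graph, cfg)
  expect_lt(max(abs(rowSums(fit$draws$u))), 1e-10)
  expect_lt(max(abs(rowSums(fit$draws$t))), 1e-10)
  expect_lt(max(abs(rowSums(fit$draws$delta))), 1e-10)
  # intervals contain their means for every summarized parameter
  expect_true(all(fit$summary$lo95 <= fit$summary$mean &
                    fit$summary$mean <= fit$summary$hi95))
})

test_that("sampler's incremental state matches the exact linear predictor", {
  fx <- small_sim(seed = 13L, n_areas = 9L, n_years = 2L)
  cfg <- mcmc_config(chains = 1L, iterations = 120L, burnin = 60L, thin = 1L,
                     seed = 2L, keep_eta = TRUE)
  # fit without the interaction block so every component of eta is
  # reconstructable from the stored draws
  fit <- fit_model(model_spec(3), fx$panel, fx$expected, fx$graph, cfg,
                   components = c("spatial", "het", "temporal", "disparity"))
  covs <- attr(fx$panel, "covariates")
  X <- scale(as.matrix(covs[-1L]))
  keep <- fx$expected$expected > 0
  cells <- data.frame(
    area = match(fx$panel$area_id, attr(fx$panel, "areas"))[keep],
    year = match(fx$panel$year, attr(fx$panel, "years"))[keep],
    eth = fx$panel$group[keep])
  for (k in c(1L, fit$n_draws)) {
    st <- parameter_state(
      alpha = fit$draws$alpha[k], delta0 = fit$draws$delta0[k],
      delta = fit$draws$delta[k, ], beta = fit$draws$beta[k, ],
      u = fit$draws$u[k, ], v = fit$draws$v[k, ], t = fit$draws$t[k, ],
      psi = matrix(0, 9L, 2L),
      tau = list(u = 1, v = 1, t = 1, psi = 1, delta = 1))
    expect_equal(fit$eta_draws[k, ], unname(linear_predictor(st, cells, X = X)),
                 tolerance = 1e-10)
  }
})
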