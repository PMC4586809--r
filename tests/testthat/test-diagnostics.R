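test_that("DIC from draws matches a hand-computed single-cell example", {
  # one cell, y = 1, e = 1, theta draws {1, e}: deviances {2, 2e - 2};
  # plug-in at mean log theta = 0.5 gives D = 2 exp(0.5) - 1
  d <- dic_from_draws(y = 1L, e = 1, eta_draws = matrix(c(0, 1), 2L, 1L))
  expect_equal(d$Dbar, exp(1), tolerance = 1e-12)
  expect_equal(d$Dhat, 2 * exp(0.5) - 1, tolerance = 1e-12)
  expect_equal(d$pD, exp(1) - (2 * exp(0.5) - 1), tolerance = 1e-12)
  expect_equal(d$DIC, d$Dbar + d$pD)
  expect_equal(round(d$pD, 5), 0.42084)
  expect_equal(d$DIC, 2 * exp(1) - 2 * exp(0.5) + 1, tolerance = 1e-12)
  expect_equal(d$DIC, 3.13912, tolerance = 1e-5)
})

test_that("degenerate posterior has pD = 0 and DIC = the plug-in deviance", {
  eta <- matrix(0.3, 10L, 4L)
  y <- c(2L, 0L, 5L, 1L); e <- c(1, 2, 3, 1)
  d <- dic_from_draws(y, e, eta)
  expect_equal(d$pD, 0, tolerance = 1e-12)
  expect_equal(d$DIC, -2 * sum(poisson_loglik(y, e * exp(0.3))),
               tolerance = 1e-12)
})

test_that("pD approximates the free parameter count in a fixed-effect fit", {
  # intercept-only model: one free parameter
  set.seed(31)
  df <- data.frame(area_id = sprintf("A%02d", 1:20), year = 0L,
                   group = rep(0:1, 10L), cancer = "x",
                   count = rpois(20L, 12), population = 1000)
  pan <- areal_panel(df, complete = TRUE)
  e <- expected_counts(pan, data.frame(cancer = "x", group = 0:1,
                                       rate = 0.012))
  g <- adjacency_graph(cbind(sprintf("A%02d", 1:19), sprintf("A%02d", 2:20)),
                       areas = attr(pan, "areas"))
  cfg <- mcmc_config(chains = 1L, iterations = 4000L, burnin = 1000L,
                     thin = 1L, seed = 6L)
  fit <- fit_model(model_spec(1), pan, e, g, cfg, components = "none")
  expect_equal(dic(fit)$pD, 1, tolerance = 0.2)
})

test_that("dic() validates the supplied data against the fit", {
  fx <- small_sim(seed = 14L, n_areas = 9L, n_years = 2L)
  cfg <- mcmc_config(chains = 1L, iterations = 200L, burnin = 100L,
                     thin = 1L, seed = 4L)
  fit <- fit_model(model_spec(1), fx$panel, fx$expected, fx$graph, cfg)
  expect_silent(dic(fit, fx$panel, fx$expected))
  other <- small_sim(seed = 99L, n_areas = 9L, n_years = 2L)
  expect_error(dic(fit, other$panel, other$expected), "does not match")
})

test_that("exceedence probabilities: basics, calibration and monotonicity", {
  expect_equal(exceedence_prob(c(2, 3, 4), 1.25), 1)
  expect_equal(exceedence_prob(c(1.0, 1.3, 1.5, 1.2), 1.25), 0.5)

  set.seed(17)
  draws <- exp(rnorm(100000))
  expect_equal(exceedence_prob(draws, 1.25), 1 - pnorm(log(1.25)),
               tolerance = 0.005 / 0.4117)
  # monotone non-increasing in the threshold
  thresholds <- c(0.8, 1, 1.25, 1.5, 2)
  probs <- vapply(thresholds, exceedence_prob, 0, draws = draws)
  expect_true(all(diff(probs) <= 0))
})

test_that("exceedence maps work at area and cell level", {
  fx <- small_sim(seed = 15L, n_areas = 9L, n_years = 2L)
  cfg <- mcmc_config(chains = 1L, iterations = 300L, burnin = 100L,
                     thin = 1L, seed = 5L, keep_eta = TRUE)
  fit <- fit_model(model_spec(3), fx$panel, fx$expected, fx$graph, cfg)
  em <- exceedence(fit, 1.25)
  expect_equal(nrow(em), 9L)
  expect_true(all(em$prob >= 0 & em$prob <= 1))
  ec <- exceedence(fit, 1.25, level = "cell")
  expect_equal(nrow(ec), nrow(fit$cells))
  # monotone in threshold at both levels
  expect_true(all(exceedence(fit, 1.5)$prob <= em$prob))

  fit1 <- fit_model(model_spec(1), fx$panel, fx$expected, fx$graph, cfg)
  expect_warning(e1 <- exceedence(fit1, 1.25), "constant")
  expect_equal(length(unique(e1$prob)), 1L)
})

test_that("compare_models ranks by DIC, order-invariantly", {
  fx <- small_sim(seed = 16L, n_areas = 16L, n_years = 3L)
  cfg <- mcmc_config(chains = 1L, iterations = 400L, burnin = 200L,
                     thin = 2L, seed = 8L)
  f1 <- fit_model(model_spec(1), fx$panel, fx$expected, fx$graph, cfg)
  f3 <- fit_model(model_spec(3), fx$panel, fx$expected, fx$graph, cfg)
  tab <- compare_models(list(f1, f3))
  expect_equal(tab$dDIC[1L], 0)
  expect_true(all(diff(tab$DIC) >= 0))
  tab2 <- compare_models(list(f3, f1))
  expect_equal(tab, tab2)
  # identical fits have zero DIC spread
  expect_equal(compare_models(list(f1, f1))$dDIC, c(0, 0))

  other <- small_sim(seed = 17L, n_areas = 16L, n_years = 3L)
  fo <- fit_model(model_spec(1), other$panel, other$expected, other$graph,
                  cfg)
  expect_error(compare_models(list(f1, fo)), "same data")
})

test_that("split R-hat and ESS behave on engineered chains", {
  set.seed(23)
  x_good <- rnorm(2000)
  chain <- rep(1:2, each = 1000L)
  expect_equal(arealdisp:::split_rhat(x_good, chain), 1, tolerance = 0.02)
  x_bad <- c(rnorm(1000), rnorm(1000, 3))
  expect_gt(arealdisp:::split_rhat(x_bad, chain), 1.2)
  # iid draws: ESS close to the draw count
  expect_gt(arealdisp:::ess(x_good, chain), 1200)
})

test_that("convergence() summarizes a fit and flags degenerate chains", {
  fx <- small_sim(seed = 18L, n_areas = 9L, n_years = 2L)
  cfg <- mcmc_config(chains = 2L, iterations = 300L, burnin = 100L,
                     thin = 1L, seed = 12L)
  fit <- fit_model(model_spec(2), fx$panel, fx$expected, fx$graph, cfg)
  cv <- convergence(fit)
  expect_true(all(c("alpha", "delta0", "tau_delta") %in% cv$parameter))
  expect_true(all(is.finite(cv$rhat)))
  # constant chain: NA with a warning
  fit$draws$alpha <- rep(1, fit$n_draws)
  expect_warning(cv2 <- convergence(fit), "constant")
  expect_true(is.na(cv2$rhat[cv2$parameter == "alpha"]))
})

test_that("prior sensitivity arms agree on a small synthetic fit", {
  fx <- small_sim(seed = 19L, n_areas = 16L, n_years = 3L)
  cfg <- mcmc_config(chains = 1L, iterations = 600L, burnin = 300L,
                     thin = 2L, seed = 13L)
  sens <- prior_sensitivity(model_spec(2), fx$panel, fx$expected, fx$graph,
                            cfg)
  expect_setequal(sens$table$parameter,
                  c("tau_u", "tau_v", "tau_t", "tau_psi", "tau_delta"))
  expect_true(all(c("parameter", "prior", "x", "density") %in%
                    names(sens$densities)))
  expect_setequal(unique(sens$densities$prior), c("gamma", "flat"))
  # same-prior arms agree within Monte Carlo error: refit gamma arm with a
  # different seed and compare delta0 summaries
  cfg2 <- cfg; cfg2$seed <- 14L
  f2 <- fit_model(model_spec(2), fx$panel, fx$expected, fx$graph, cfg2)
  s1 <- summarize_draws(sens$fits$gamma$draws$delta0)
  s2 <- summarize_draws(f2$draws$delta0)
  expect_lt(abs(s1["mean"] - s2["mean"]), 0.1)
})
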