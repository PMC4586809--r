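# Expensive replicate experiments shared across acceptance tests, computed
# once per test run.
.exp_cache <- new.env(parent = emptyenv())

# Panel-scale recovery/selection experiment: replicate panels at the default
# generator conditions (254 areas x 9 years x 2 groups, Model 3 truth with
# delta0 = 0.15), each fit under Models 3 and 1.
recovery_experiment <- function(n_rep = 20L) {
  key <- paste0("recovery", n_rep)
  if (!is.null(.exp_cache[[key]])) return(.exp_cache[[key]])
  cfg <- gen_config()
  mc <- mcmc_config(chains = 1L, iterations = 3000L, burnin = 1500L,
                    thin = 3L, seed = 1L, keep_eta = FALSE)
  res <- lapply(seq_len(n_rep), function(r) {
    sim <- simulate_dataset(cfg, seed = 1000L + r)
    pan <- panel_stratum(sim$panel, "digestive")
    expd <- expected_counts(pan, attr(sim$expected, "rates"))
    mc$seed <- r
    f3 <- fit_model(model_spec(3), pan, expd, sim$graph, mc)
    f1 <- fit_model(model_spec(1), pan, expd, sim$graph, mc)
    s <- summarize_draws(f3$draws$delta0)
    data.frame(d0 = s["mean"], lo = s["lo95"], hi = s["hi95"],
               dic3 = dic(f3)$DIC, dic1 = dic(f1)$DIC,
               truth = cfg$cancers$digestive$delta0)
  })
  .exp_cache[[key]] <- do.call(rbind, res)
  .exp_cache[[key]]
}

# Reduced-size interval-coverage experiment (100 areas x 5 years).
coverage_experiment <- function(n_rep = 50L) {
  key <- paste0("coverage", n_rep)
  if (!is.null(.exp_cache[[key]])) return(.exp_cache[[key]])
  cfg <- gen_config(n_areas = 100L, n_years = 5L)
  mc <- mcmc_config(chains = 1L, iterations = 4000L, burnin = 2000L,
                    thin = 2L, seed = 1L, keep_eta = FALSE)
  res <- lapply(seq_len(n_rep), function(r) {
    sim <- simulate_dataset(cfg, seed = 2000L + r)
    pan <- panel_stratum(sim$panel, "digestive")
    expd <- expected_counts(pan, attr(sim$expected, "rates"))
    mc$seed <- r
    f3 <- fit_model(model_spec(3), pan, expd, sim$graph, mc)
    s <- summarize_draws(f3$draws$delta0)
    data.frame(lo = s["lo95"], hi = s["hi95"],
               truth = cfg$cancers$digestive$delta0)
  })
  .exp_cache[[key]] <- do.call(rbind, res)
  .exp_cache[[key]]
}
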