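#' Deviance information criterion from raw draws
#'
#' `Dbar` is the posterior mean of the deviance `-2 log p(y | theta)`; the
#' plug-in deviance is evaluated at the posterior mean of each cell's log
#' relative risk (the canonical-scale plug-in); `pD = Dbar - Dhat` and
#' `DIC = Dbar + pD`.
#'
#' @param y,e observed counts and expected counts per cell.
#' @param eta_draws draws x cells matrix of log relative risks.
#' @return list with `Dbar`, `pD`, `DIC`, `Dhat`.
#' @export
dic_from_draws <- function(y, e, eta_draws) {
  eta_draws <- as.matrix(eta_draws)
  if (nrow(eta_draws) < 1L) stop("no draws")
  stopifnot(ncol(eta_draws) == length(y), length(y) == length(e))
  dev <- apply(eta_draws, 1L, function(eta)
    -2 * sum(poisson_loglik(y, e * exp(eta))))
  dbar <- mean(dev)
  dhat <- -2 * sum(poisson_loglik(y, e * exp(colMeans(eta_draws))))
  pd <- dbar - dhat
  list(Dbar = dbar, pD = pd, DIC = dbar + pd, Dhat = dhat)
}

#' Deviance information criterion of a fit
#'
#' Uses the deviance draws and per-cell posterior mean linear predictor
#' retained by [fit_model()]; `panel`/`expected` are accepted for interface
#' compatibility and, when supplied, validated against the stored cells.
#'
#' @param fit a [fit_model()] result.
#' @param panel,expected optional; must match the data the fit was run on.
#' @return An object of class `dic_report`: `Dbar`, `pD`, `DIC`, `Dhat`,
#'   `model`, and `negative_pD` flag (a negative effective parameter count is
#'   reported, not hidden).
#' @export
dic <- function(fit, panel = NULL, expected = NULL) {
  if (length(fit$deviance) == 0L) stop("fit retains no deviance draws")
  if (!is.null(panel)) {
    keep <- if (!is.null(expected)) expected$expected > 0
            else rep(TRUE, nrow(panel))
    if (sum(panel$count[keep]) != sum(fit$cells$count))
      stop("panel does not match the data the model was fit to")
  }
  dbar <- mean(fit$deviance)
  dhat <- -2 * sum(poisson_loglik(fit$cells$count,
                                  fit$cells$expected * exp(fit$eta_mean)))
  pd <- dbar - dhat
  structure(list(Dbar = dbar, pD = pd, DIC = dbar + pd, Dhat = dhat,
                 model = fit$spec$model, negative_pD = pd < 0),
            class = "dic_report")
}

#' @export
print.dic_report <- function(x, ...) {
  cat(sprintf("Model %d: Dbar = %.1f, pD = %.1f, DIC = %.1f%s\n", x$model,
              x$Dbar, x$pD, x$DIC,
              if (x$negative_pD) "  [warning: negative pD]" else ""))
  invisible(x)
}

#' Posterior exceedence probability of a vector of draws
#'
#' @param draws posterior draws of a relative-risk quantity.
#' @param threshold critical risk level `theta*`.
#' @return Fraction of draws strictly above `threshold`.
#' @export
exceedence_prob <- function(draws, threshold) {
  if (length(draws) == 0L) stop("no draws")
  mean(draws > threshold)
}

#' Exceedence-probability cluster map
#'
#' The Bayesian cluster-detection summary `Pr(theta > theta*)`. At the
#' default `"area"` level the quantity is the per-area disparity relative
#' risk `exp(delta0 + delta_i)` (where is the focal group's risk more than
#' `theta*` times the reference group's?); at the `"cell"` level it is the
#' fitted relative risk `exp(log theta)` of each (area, year, group) cell,
#' which requires `keep_eta = TRUE` at fit time.
#'
#' @param fit a [fit_model()] result.
#' @param threshold `theta*`; defaults to the spec's threshold (1.25 —
#'   focal risk 25% above reference).
#' @param level `"area"` or `"cell"`.
#' @return data.frame of exceedence probabilities with a `band` column
#'   cutting at 0.8 and 0.95 (presentation bands; `[0.95, 1]` flags a
#'   cluster).
#' @export
exceedence <- function(fit, threshold = fit$spec$threshold,
                       level = c("area", "cell")) {
  level <- match.arg(level)
  stopifnot(threshold > 0)
  if (level == "area") {
    if (!"disparity" %in% fit$components)
      stop("fit has no disparity component")
    if (fit$spec$model == 1L)
      warning("Model 1 has a single statewide disparity; the map is constant")
    n <- length(fit$areas)
    dmat <- if (fit$spec$model >= 2L)
      exp(fit$draws$delta0 + fit$draws$delta)
    else exp(matrix(fit$draws$delta0, nrow = fit$n_draws, ncol = n))
    out <- data.frame(area_id = fit$areas,
                      prob = colMeans(dmat > threshold),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(fit$eta_draws))
      stop("cell-level exceedence requires keep_eta = TRUE at fit time")
    out <- fit$cells[c("area_id", "year", "group")]
    out$prob <- colMeans(exp(fit$eta_draws) > threshold)
  }
  out$band <- cut(out$prob, c(-Inf, 0.8, 0.95, Inf),
                  labels = c("[0,0.8)", "[0.8,0.95)", "[0.95,1]"))
  attr(out, "threshold") <- threshold
  out
}

#' Rank fitted models by DIC
#'
#' @param fits list of [fit_model()] results on the same data.
#' @return data.frame sorted ascending by DIC with a `dDIC` column (lowest
#'   DIC — the preferred model — first).
#' @export
compare_models <- function(fits) {
  if (length(fits) < 1L) stop("no fits supplied")
  fp <- vapply(fits, `[[`, "", "fingerprint")
  if (length(unique(fp)) != 1L)
    stop("fits were not run on the same data")
  rows <- lapply(fits, function(f) {
    d <- dic(f)
    data.frame(model = f$spec$model, Dbar = d$Dbar, pD = d$pD, DIC = d$DIC)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$DIC), , drop = FALSE]
  out$dDIC <- out$DIC - out$DIC[1L]
  rownames(out) <- NULL
  out
}

#' Precision prior sensitivity analysis
#'
#' Fits the same model twice — under the vague Gamma precision priors and
#' under flat `Uniform(0, upper]` priors — and reports side-by-side posterior
#' summaries for every precision, an interval-overlap indicator, and the
#' marginal posterior densities for plotting.
#'
#' @param spec a [model_spec()] (its `tau_prior` is overridden per arm).
#' @param panel,expected,graph as for [fit_model()].
#' @param config an [mcmc_config()].
#' @return list with `table` (per-precision means/intervals per arm and
#'   `overlap`), `densities` (tidy data.frame: parameter, prior, x, density),
#'   and the two fits.
#' @export
prior_sensitivity <- function(spec, panel, expected, graph,
                              config = mcmc_config()) {
  arms <- list(
    gamma = model_spec(spec$model, spec$fixed_prec, "gamma",
                       spec$tau_shape, spec$tau_rate, spec$tau_upper,
                       spec$threshold, spec$standardize_covariates),
    flat = model_spec(spec$model, spec$fixed_prec, "flat",
                      spec$tau_shape, spec$tau_rate, spec$tau_upper,
                      spec$threshold, spec$standardize_covariates))
  fits <- lapply(arms, function(sp)
    fit_model(sp, panel, expected, graph, config))
  taus <- colnames(fits$gamma$draws$tau)
  rows <- lapply(taus, function(tn) {
    sg <- summarize_draws(fits$gamma$draws$tau[, tn])
    sf <- summarize_draws(fits$flat$draws$tau[, tn])
    data.frame(parameter = tn,
               mean_gamma = sg["mean"], lo_gamma = sg["lo95"],
               hi_gamma = sg["hi95"],
               mean_flat = sf["mean"], lo_flat = sf["lo95"],
               hi_flat = sf["hi95"],
               overlap = sg["lo95"] <= sf["hi95"] & sf["lo95"] <= sg["hi95"],
               stringsAsFactors = FALSE)
  })
  dens <- do.call(rbind, unlist(lapply(taus, function(tn)
    lapply(names(fits), function(arm) {
      d <- stats::density(fits[[arm]]$draws$tau[, tn])
      data.frame(parameter = tn, prior = arm, x = d$x, density = d$y,
                 stringsAsFactors = FALSE)
    })), recursive = FALSE))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, densities = dens, fits = fits)
}

# Split-chain potential scale reduction factor.
split_rhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    m <- length(v) %/% 2L
    list(v[seq_len(m)], v[m + seq_len(m)])
  }), recursive = FALSE)
  halves <- halves[lengths(halves) >= 2L]
  if (length(halves) < 2L) return(NA_real_)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(n)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via the initial positive sequence of autocorrelations,
# pooled across chains.
ess <- function(x, chain = rep(1L, length(x))) {
  chains <- split(x, chain)
  n <- min(lengths(chains))
  if (n < 4L) return(NA_real_)
  chains <- lapply(chains, function(v) v[seq_len(n)])
  acfs <- vapply(chains, function(v) {
    if (stats::var(v) == 0) return(rep(NA_real_, min(n - 1L, 100L)))
    stats::acf(v, lag.max = min(n - 1L, 100L), plot = FALSE,
               demean = TRUE)$acf[-1L]
  }, numeric(min(n - 1L, 100L)))
  rho <- rowMeans(as.matrix(acfs))
  if (anyNA(rho)) return(NA_real_)
  s <- 0
  for (k in seq(1L, length(rho) - 1L, by = 2L)) {
    pair <- rho[k] + rho[k + 1L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
  }
  length(x) / (1 + 2 * s)
}

#' Convergence diagnostics
#'
#' Split-chain potential scale reduction (R-hat) and effective sample size
#' for every scalar parameter block (intercept, disparity, covariate effects,
#' precisions). Constant chains are degenerate and reported as `NA` with a
#' warning.
#'
#' @param fit a [fit_model()] result.
#' @param rhat_warn flag parameters with R-hat above this value.
#' @return data.frame with `parameter`, `rhat`, `ess`, `flagged`.
#' @export
convergence <- function(fit, rhat_warn = 1.05) {
  if (fit$n_draws < 4L) stop("too few draws for convergence diagnostics")
  params <- list(alpha = fit$draws$alpha)
  if ("disparity" %in% fit$components) params$delta0 <- fit$draws$delta0
  if (!is.null(fit$draws$beta))
    for (k in seq_len(ncol(fit$draws$beta)))
      params[[colnames(fit$draws$beta)[k] %||% paste0("beta", k)]] <-
        fit$draws$beta[, k]
  for (k in colnames(fit$draws$tau)) params[[k]] <- fit$draws$tau[, k]
  rows <- lapply(names(params), function(nm) {
    x <- params[[nm]]
    if (stats::var(x) == 0) {
      warning("constant chain for ", nm, "; diagnostics degenerate")
      return(data.frame(parameter = nm, rhat = NA_real_, ess = NA_real_,
                        flagged = NA, stringsAsFactors = FALSE))
    }
    r <- split_rhat(x, fit$chain)
    data.frame(parameter = nm, rhat = r, ess = ess(x, fit$chain),
               flagged = is.finite(r) && r > rhat_warn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
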