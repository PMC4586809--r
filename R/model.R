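#' Specify one of the three disparity models
#'
#' All three models share a log-linear Poisson structure for the relative
#' risk of cell (area i, year j, group k):
#' `log theta = alpha + delta_i * eth + X beta + u_i + v_i + t_j + psi_ij`
#' with a BYM convolution (ICAR `u` plus exchangeable `v`), an exchangeable
#' year effect `t`, and an independent space-time interaction `psi`.
#' They differ only in the disparity coefficient:
#' \describe{
#'   \item{Model 1}{a single statewide coefficient `delta0` (no `delta_i`).}
#'   \item{Model 2}{`delta0` plus exchangeable per-area deviations
#'     `delta_i ~ N(0, tau_delta)` (random slopes).}
#'   \item{Model 3}{`delta0` plus ICAR-smoothed deviations (a spatially
#'     varying coefficient).}
#' }
#' Normal priors are parameterized by mean and precision (`tau = 1/sigma^2`).
#' Fixed effects get vague `N(0, 1e-4)` precision priors; the intercept gets
#' an improper flat prior; precisions get `Gamma(0.5, 0.0005)` priors by
#' default, with a flat `Uniform(0, upper]` alternative for sensitivity
#' analysis.
#'
#' @param model 1, 2 or 3.
#' @param fixed_prec prior precision for fixed effects (`delta0`, `beta`).
#' @param tau_prior `"gamma"` or `"flat"` prior family for all precisions.
#' @param tau_shape,tau_rate Gamma prior shape and rate.
#' @param tau_upper upper bound of the flat precision prior.
#' @param threshold exceedence threshold on the relative-risk scale.
#' @param standardize_covariates z-score covariates before fitting.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model = 3L, fixed_prec = 1e-4,
                       tau_prior = c("gamma", "flat"),
                       tau_shape = 0.5, tau_rate = 0.0005, tau_upper = 1e5,
                       threshold = 1.25, standardize_covariates = TRUE) {
  tau_prior <- match.arg(tau_prior)
  model <- as.integer(model)
  if (!model %in% 1:3) stop("model must be 1, 2 or 3")
  stopifnot(fixed_prec > 0, tau_shape > 0, tau_rate > 0, tau_upper > 0,
            threshold > 0)
  structure(list(model = model, fixed_prec = fixed_prec,
                 tau_prior = tau_prior, tau_shape = tau_shape,
                 tau_rate = tau_rate, tau_upper = tau_upper,
                 threshold = threshold,
                 standardize_covariates = isTRUE(standardize_covariates)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  lab <- c("fixed disparity", "exchangeable random-slope disparity",
           "ICAR spatially varying disparity")[x$model]
  cat(sprintf("model_spec: Model %d (%s)\n", x$model, lab))
  cat(sprintf("  precision prior: %s; exceedence threshold %.3g\n",
              if (x$tau_prior == "gamma")
                sprintf("Gamma(%g, %g)", x$tau_shape, x$tau_rate)
              else sprintf("Uniform(0, %g]", x$tau_upper),
              x$threshold))
  invisible(x)
}

#' Serialize / deserialize a model specification
#'
#' @param spec a [model_spec()].
#' @param file optional path; if given the YAML is written there.
#' @return `spec_to_yaml`: YAML string (invisibly if written to file);
#'   `spec_from_yaml`: a [model_spec()].
#' @export
spec_to_yaml <- function(spec, file = NULL) {
  txt <- yaml::as.yaml(unclass(spec))
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' @rdname spec_to_yaml
#' @param x YAML string or path to a YAML file.
#' @export
spec_from_yaml <- function(x) {
  lst <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  do.call(model_spec, lst)
}

#' Assemble a parameter state
#'
#' Container for one configuration of all model parameters; used by the
#' log-posterior evaluator, the sampler, and the synthetic-data generator.
#'
#' @param alpha intercept (log baseline relative risk).
#' @param delta0 mean disparity coefficient (log relative-risk scale).
#' @param delta per-area disparity deviations (NULL for Model 1).
#' @param beta covariate coefficients.
#' @param u ICAR spatial effects (sum-to-zero).
#' @param v exchangeable spatial heterogeneity.
#' @param t exchangeable year effects (sum-to-zero).
#' @param psi space-time interaction, an `n_areas x n_years` matrix.
#' @param tau named list/vector of precisions: `u`, `v`, `t`, `psi`, and
#'   `delta` for Models 2-3.
#' @return An object of class `parameter_state`.
#' @export
parameter_state <- function(alpha = 0, delta0 = 0, delta = NULL,
                            beta = numeric(0), u, v, t, psi, tau) {
  psi <- as.matrix(psi)
  stopifnot(length(u) == length(v), nrow(psi) == length(u),
            ncol(psi) == length(t))
  tau <- as.list(tau)
  if (any(unlist(tau) <= 0)) stop("precisions must be strictly positive")
  structure(list(alpha = alpha, delta0 = delta0, delta = delta,
                 beta = beta, u = u, v = v, t = t, psi = psi, tau = tau),
            class = "parameter_state")
}

#' Linear predictor (log relative risk) for panel cells
#'
#' `log theta = alpha + (delta0 + delta_i) * eth + x_i' beta + u_i + v_i +
#' t_j + psi_ij`; for Model 1 the `delta_i` term is absent. The reference
#' group (`eth = 0`) receives no disparity contribution.
#'
#' @param state a [parameter_state()].
#' @param cells data.frame with integer columns `area` (1-based area index),
#'   `year` (1-based year index) and `eth` (0/1).
#' @param X optional `n_areas x p` covariate matrix (omit or NULL when
#'   `state$beta` is empty).
#' @return Numeric vector of log relative risks, one per row of `cells`.
#' @export
linear_predictor <- function(state, cells, X = NULL) {
  n <- length(state$u); J <- length(state$t)
  if (any(cells$area < 1L | cells$area > n) ||
      any(cells$year < 1L | cells$year > J))
    stop("cell indices out of range for the parameter state")
  d <- if (is.null(state$delta)) rep(0, n) else {
    if (length(state$delta) != n) stop("delta dimension mismatch")
    state$delta
  }
  xb <- if (length(state$beta) > 0L) {
    if (is.null(X) || ncol(X) != length(state$beta))
      stop("covariate matrix does not match beta")
    as.vector(X %*% state$beta)
  } else rep(0, n)
  i <- cells$area; j <- cells$year
  state$alpha + (state$delta0 + d[i]) * cells$eth + xb[i] +
    state$u[i] + state$v[i] + state$t[j] + state$psi[cbind(i, j)]
}

#' Poisson log-likelihood of a count
#'
#' `log p(y | mu) = -mu + y log(mu) - log(y!)` — the exact log probability,
#' including the normalizing constant, so deviances are comparable across
#' models.
#'
#' @param y non-negative integer count(s).
#' @param mu positive mean(s), `e * theta`.
#' @return log probability (vectorized).
#' @export
poisson_loglik <- function(y, mu) {
  if (any(mu <= 0)) stop("mu must be strictly positive")
  -mu + y * log(mu) - lgamma(y + 1)
}

#' Unnormalized ICAR log density
#'
#' The intrinsic conditional autoregressive (Besag) prior:
#' `-(tau/2) * sum over edges (x_i - x_j)^2`, equivalently the degenerate
#' Gaussian with precision matrix `tau * (D - W)` restricted to the
#' sum-to-zero subspace. Each area's full conditional is Normal with mean the
#' average of its neighbours and variance `1 / (tau * n_i)`. Isolated areas
#' contribute nothing.
#'
#' @param x numeric vector, one value per area.
#' @param tau positive precision.
#' @param graph an [adjacency_graph()] over the same areas.
#' @return Scalar unnormalized log density.
#' @export
icar_logdensity <- function(x, tau, graph) {
  if (length(x) != length(graph$areas))
    stop("effect vector length does not match graph")
  if (tau <= 0) stop("tau must be strictly positive")
  e <- graph$edges
  if (nrow(e) == 0L) return(0)
  -(tau / 2) * sum((x[e[, 1L]] - x[e[, 2L]])^2)
}

#' IID normal log prior (mean zero, common precision)
#'
#' `sum_i [ (1/2) log(tau) - (1/2) log(2*pi) - (tau/2) x_i^2 ]` under the
#' mean-precision parameterization.
#'
#' @param x numeric vector of effects.
#' @param tau positive precision.
#' @return Scalar log density.
#' @export
iid_normal_logprior <- function(x, tau) {
  if (tau <= 0) stop("tau must be strictly positive")
  sum(stats::dnorm(x, mean = 0, sd = 1 / sqrt(tau), log = TRUE))
}

#' Gamma log prior for a precision
#'
#' Shape-rate parameterization; the package default prior for all precision
#' parameters is `Gamma(0.5, 0.0005)`.
#'
#' @param tau positive precision value.
#' @param shape,rate Gamma hyperparameters.
#' @return Scalar log density.
#' @export
gamma_logprior <- function(tau, shape = 0.5, rate = 0.0005) {
  if (any(tau <= 0)) stop("tau must be strictly positive")
  stats::dgamma(tau, shape = shape, rate = rate, log = TRUE)
}

# Internal cell-level representation used by log_posterior and the sampler:
# a single cancer stratum with e > 0 cells only.
build_model_data <- function(panel, expected, graph, spec) {
  cancers <- attr(panel, "cancers")
  if (length(cancers) != 1L)
    stop("fit one cancer stratum at a time (see panel_stratum())")
  check_graph_panel(graph, panel)
  areas <- attr(panel, "areas")
  # align graph area order to the panel's
  perm <- match(areas, graph$areas)
  if (!identical(perm, seq_along(areas))) {
    e <- graph$edges
    inv <- match(graph$areas, areas)
    graph <- adjacency_graph(cbind(areas[inv[e[, 1L]]], areas[inv[e[, 2L]]]),
                             areas = areas)
  }
  years <- attr(panel, "years")
  stopifnot(nrow(panel) == nrow(expected))
  keep <- expected$expected > 0
  if (!any(keep)) stop("no cells with positive expected counts")
  covs <- attr(panel, "covariates")
  X <- NULL
  if (!is.null(covs)) {
    Xr <- as.matrix(covs[setdiff(names(covs), "area_id")])
    storage.mode(Xr) <- "double"
    if (spec$standardize_covariates) {
      mu <- colMeans(Xr); s <- apply(Xr, 2L, stats::sd)
      s[s == 0] <- 1
      X <- sweep(sweep(Xr, 2L, mu), 2L, s, "/")
    } else X <- Xr
  }
  list(y = panel$count[keep], e = expected$expected[keep],
       ai = match(panel$area_id, areas)[keep],
       yj = match(panel$year, years)[keep],
       g = panel$group[keep],
       X = X, graph = graph, areas = areas, years = years,
       n = length(areas), J = length(years),
       ncomp = max(graph_components(graph)),
       fingerprint = paste(length(panel$count[keep]), sum(panel$count[keep]),
                           signif(sum(expected$expected[keep]), 12)))
}

#' Log posterior of a full parameter state
#'
#' Sum of the Poisson log-likelihood over all cells with positive expected
#' count and all prior log densities implied by the model specification: the
#' intercept's flat prior contributes zero; `delta0` and `beta` carry vague
#' normal priors; `u` is ICAR; `v`, `t`, `psi` are exchangeable normal;
#' `delta` is exchangeable (Model 2) or ICAR (Model 3); precisions carry
#' Gamma or flat priors. Used directly by tests and as the reference against
#' which the sampler's incremental updates are validated.
#'
#' @param state a [parameter_state()].
#' @param panel single-stratum [areal_panel()].
#' @param expected aligned [expected_counts()].
#' @param graph an [adjacency_graph()].
#' @param spec a [model_spec()].
#' @param likelihood_only if TRUE, return just the Poisson term.
#' @return Scalar log posterior (unnormalized).
#' @export
log_posterior <- function(state, panel, expected, graph, spec,
                          likelihood_only = FALSE) {
  md <- build_model_data(panel, expected, graph, spec)
  eta <- linear_predictor(state,
                          data.frame(area = md$ai, year = md$yj, eth = md$g),
                          X = md$X)
  ll <- sum(poisson_loglik(md$y, md$e * exp(eta)))
  if (likelihood_only) return(ll)
  lp <- ll
  lp <- lp + iid_normal_logprior(state$delta0, spec$fixed_prec)
  if (length(state$beta) > 0L)
    lp <- lp + iid_normal_logprior(state$beta, spec$fixed_prec)
  lp <- lp + icar_logdensity(state$u, state$tau$u, md$graph)
  lp <- lp + iid_normal_logprior(state$v, state$tau$v)
  lp <- lp + iid_normal_logprior(state$t, state$tau$t)
  lp <- lp + iid_normal_logprior(as.vector(state$psi), state$tau$psi)
  taus <- c(u = state$tau$u, v = state$tau$v, t = state$tau$t,
            psi = state$tau$psi)
  if (spec$model >= 2L) {
    if (is.null(state$delta)) stop("Models 2-3 require delta deviations")
    lp <- lp + if (spec$model == 2L)
      iid_normal_logprior(state$delta, state$tau$delta)
    else icar_logdensity(state$delta, state$tau$delta, md$graph)
    taus <- c(taus, delta = state$tau$delta)
  }
  lp + sum(if (spec$tau_prior == "gamma")
    gamma_logprior(taus, spec$tau_shape, spec$tau_rate)
  else ifelse(taus <= spec$tau_upper, 0, -Inf))
}
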