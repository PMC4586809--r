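#' MCMC sampler configuration
#'
#' @param chains number of independent chains.
#' @param iterations sweeps per chain (including burn-in).
#' @param burnin sweeps discarded per chain; proposal scales adapt only
#'   during burn-in and are frozen afterwards.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; chain streams are derived from it, and identical
#'   seeds give identical output.
#' @param keep_eta store the per-cell log relative-risk draws (needed for
#'   cell-level credible intervals and cell-level exceedence maps; memory
#'   grows with draws x cells).
#' @param accept_target adapted acceptance rate for random-walk blocks.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 2L, iterations = 10000L, burnin = 5000L,
                        thin = 5L, seed = 1L, keep_eta = TRUE,
                        accept_target = 0.44) {
  stopifnot(chains >= 1L, iterations > burnin, burnin >= 0L, thin >= 1L,
            accept_target > 0, accept_target < 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed), keep_eta = isTRUE(keep_eta),
                 accept_target = accept_target),
            class = "mcmc_config")
}

# Per-group sums; groups indexed 1..nbins, cells ordered arbitrarily.
agg_sum <- function(x, idx, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, idx, reorder = FALSE)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fit a disparity model by adaptive Metropolis-within-Gibbs
#'
#' Samples the posterior of a single-stratum panel under the chosen model.
#' The intercept is drawn exactly from its conjugate (log-Gamma) conditional;
#' `delta0` and `beta` use adaptive random-walk steps; the random-effect
#' blocks use element-wise random-walk steps, updated simultaneously where
#' their full conditionals are independent (exchangeable blocks, and ICAR
#' blocks within color classes of the neighbour graph); precisions are drawn
#' from their conjugate Gamma (or upper-truncated Gamma, under the flat
#' prior) conditionals. Sum-to-zero constraints on `u`, `t` and (Models 2-3)
#' `delta` are enforced by recentering each sweep, with the means absorbed
#' into `alpha` / `delta0` so the linear predictor is unchanged.
#'
#' @param spec a [model_spec()].
#' @param panel single-stratum [areal_panel()] (see [panel_stratum()]).
#' @param expected aligned [expected_counts()]; cells with zero expected
#'   count are excluded from the likelihood.
#' @param graph an [adjacency_graph()] over the panel's areas.
#' @param config an [mcmc_config()].
#' @param components random-effect blocks to include: any of `"spatial"`
#'   (`u`), `"het"` (`v`), `"temporal"` (`t`), `"interaction"` (`psi`),
#'   `"disparity"` (`delta0`/`delta`). Excluded blocks are fixed at zero —
#'   useful for degenerate validation fits; `"none"` gives an intercept-only
#'   (plus covariates, if present) model.
#' @return An object of class `disparity_fit` with retained draws per block,
#'   posterior summaries, deviance draws, acceptance rates, and the config.
#' @export
fit_model <- function(spec, panel, expected, graph, config = mcmc_config(),
                      components = c("spatial", "het", "temporal",
                                     "interaction", "disparity")) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "mcmc_config"))
  if (length(components) == 0L || identical(components, "none"))
    components <- character(0)
  else
    components <- match.arg(components, several.ok = TRUE)
  md <- build_model_data(panel, expected, graph, spec)
  if (sum(md$y) == 0L) stop("panel has no cases; intercept is unbounded")

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$chains)
  runs <- lapply(seq_len(config$chains), function(ch)
    run_chain(md, spec, config, components, chain_seeds[ch]))

  K <- (config$iterations - config$burnin) %/% config$thin
  cat_draws <- function(name) do.call(rbind, lapply(runs, `[[`, name))
  draws <- list(alpha = unlist(lapply(runs, `[[`, "alpha")),
                delta0 = unlist(lapply(runs, `[[`, "delta0")),
                beta = cat_draws("beta"), t = cat_draws("t"),
                u = cat_draws("u"), v = cat_draws("v"),
                delta = if (spec$model >= 2L) cat_draws("delta") else NULL,
                tau = cat_draws("tau"))
  eta_draws <- if (config$keep_eta) cat_draws("eta") else NULL
  eta_mean <- Reduce(`+`, lapply(runs, `[[`, "eta_sum")) /
    (K * config$chains)
  theta_mean <- Reduce(`+`, lapply(runs, `[[`, "theta_sum")) /
    (K * config$chains)
  psi_mean <- Reduce(`+`, lapply(runs, `[[`, "psi_sum")) / (K * config$chains)
  accept <- Reduce(`+`, lapply(runs, `[[`, "accept")) / config$chains

  fit <- structure(list(
    draws = draws, eta_draws = eta_draws, eta_mean = eta_mean,
    theta_mean = theta_mean, psi_mean = psi_mean,
    deviance = unlist(lapply(runs, `[[`, "deviance")),
    chain = rep(seq_len(config$chains), each = K),
    cells = data.frame(area_id = md$areas[md$ai],
                       year = md$years[md$yj], group = md$g,
                       count = md$y, expected = md$e,
                       stringsAsFactors = FALSE),
    accept = accept, spec = spec, config = config,
    components = components, areas = md$areas, years = md$years,
    n_draws = K * config$chains, fingerprint = md$fingerprint),
    class = "disparity_fit")
  fit$summary <- fit_summary(fit)
  fit
}

# One MCMC chain. Maintains the cell-level linear predictor eta and mean mu
# incrementally; recomputes eta from scratch periodically to cap float drift.
run_chain <- function(md, spec, config, components, seed) {
  set.seed(seed)
  y <- md$y; e <- md$e
  ai <- md$ai; yj <- md$yj; g <- md$g
  n <- md$n; J <- md$J
  ncell <- length(y)
  graph <- md$graph
  use <- function(w) w %in% components
  model <- spec$model

  foc <- which(g == 1L)
  py_idx <- (yj - 1L) * n + ai
  sum_y <- sum(y)
  ysum_a <- agg_sum(y, ai, n)
  ysum_t <- agg_sum(y, yj, J)
  ysum_py <- agg_sum(y, py_idx, n * J)
  ysum_fa <- agg_sum(y[foc], ai[foc], n)
  sum_y_foc <- sum(y[foc])
  deg <- graph$n
  island <- deg == 0L
  nonisl <- which(!island)
  icar_df <- n - md$ncomp  # rank of D - W
  col_u <- graph_coloring(graph)
  classes <- lapply(sort(unique(col_u[nonisl])),
                    function(cc) nonisl[col_u[nonisl] == cc])
  cls_cells <- lapply(classes, function(cls) which(ai %in% cls))
  cls_cells_foc <- lapply(classes, function(cls)
    foc[ai[foc] %in% cls])
  edges <- graph$edges
  nb <- graph$nb

  has_X <- !is.null(md$X) && ncol(md$X) > 0L
  p <- if (has_X) ncol(md$X) else 0L
  Xcell <- if (has_X) md$X[ai, , drop = FALSE] else NULL
  syx <- if (has_X) as.vector(crossprod(Xcell, y)) else numeric(0)

  # --- initial state ---
  # Random-effect blocks start at small non-zero values: starting them at
  # exactly zero makes the first conjugate precision draw degenerate (tiny
  # quadratic form -> enormous tau), which pins the block near zero — a
  # quasi-absorbing state, worst under the flat precision prior. Precision
  # updates are also held at their initial values for a short warm-up.
  alpha <- log(sum_y / sum(e))
  delta0 <- 0
  beta <- numeric(p)
  init_sd <- 0.05
  u <- numeric(n); v <- numeric(n); tt <- numeric(J); psi <- numeric(n * J)
  if (use("spatial")) {
    u <- stats::rnorm(n, 0, init_sd); u[island] <- 0
    u <- u - mean(u[nonisl])
  }
  if (use("het")) v <- stats::rnorm(n, 0, init_sd)
  if (use("temporal")) {
    tt <- stats::rnorm(J, 0, init_sd); tt <- tt - mean(tt)
  }
  if (use("interaction")) psi <- stats::rnorm(n * J, 0, init_sd)
  delta <- if (model >= 2L && use("disparity")) {
    d0i <- stats::rnorm(n, 0, init_sd)
    if (model == 3L) d0i[island] <- 0
    d0i - mean(d0i[nonisl])
  } else if (model >= 2L) numeric(n) else NULL
  tau_init <- if (spec$tau_prior == "gamma")
    spec$tau_shape / spec$tau_rate else 1000
  tau <- list(u = tau_init, v = tau_init, t = tau_init, psi = tau_init,
              delta = if (model >= 2L) tau_init else NULL)
  tau_warmup <- 25L

  eta <- alpha + (delta0 + if (model >= 2L) delta[ai] else 0) * g +
    u[ai] + v[ai] + tt[yj] + psi[py_idx]
  mu <- e * exp(eta)
  if (any(!is.finite(mu))) stop("non-finite posterior at initialization")

  # proposal scales (adapted during burn-in, then frozen)
  sc <- list(beta = rep(0.05, p), delta0 = 0.05, u = 0.1, v = 0.1,
             t = 0.05, psi = 0.1, delta = 0.1)
  target <- config$accept_target

  K <- (config$iterations - config$burnin) %/% config$thin
  out <- list(alpha = numeric(K), delta0 = numeric(K),
              beta = matrix(NA_real_, K, p,
                            dimnames = list(NULL, colnames(md$X))),
              t = matrix(NA_real_, K, J),
              u = matrix(NA_real_, K, n), v = matrix(NA_real_, K, n),
              delta = if (model >= 2L) matrix(NA_real_, K, n),
              tau = matrix(NA_real_, K, if (model >= 2L) 5L else 4L,
                           dimnames = list(NULL,
                             c("tau_u", "tau_v", "tau_t", "tau_psi",
                               if (model >= 2L) "tau_delta"))),
              eta = if (config$keep_eta) matrix(NA_real_, K, ncell),
              deviance = numeric(K),
              eta_sum = numeric(ncell), theta_sum = numeric(ncell),
              psi_sum = numeric(n * J))
  acc_n <- c(beta = 0, delta0 = 0, u = 0, v = 0, t = 0, psi = 0, delta = 0)
  acc_d <- acc_n

  draw_tau <- function(df, quad) {
    if (spec$tau_prior == "gamma")
      stats::rgamma(1L, shape = spec$tau_shape + df / 2,
                    rate = spec$tau_rate + quad / 2)
    else {
      sh <- df / 2 + 1; rt <- quad / 2
      if (rt <= 0) return(spec$tau_upper * stats::runif(1L))
      pm <- stats::pgamma(spec$tau_upper, sh, rate = rt)
      stats::qgamma(stats::runif(1L) * pm, sh, rate = rt)
    }
  }

  # Joint scaling move on a hierarchical block: (x, tau) -> (c x, tau / c^2).
  # The Gaussian prior density times the Jacobian of the map reduces to
  # c^(-2) for any block rank, so only the likelihood and the tau hyperprior
  # enter the acceptance ratio. This lets a block escape the degenerate
  # regime (effects collapsed at zero, precision at the prior's upper range)
  # that element-wise updates with adapted step sizes cannot leave.
  scale_move <- function(x, tau, cells, xcell) {
    s <- stats::rnorm(1L, 0, 0.4)
    cc <- exp(s)
    tau_new <- tau / cc^2
    lpr <- if (spec$tau_prior == "gamma")
      (spec$tau_shape - 1) * log(tau_new / tau) -
        spec$tau_rate * (tau_new - tau)
    else if (tau_new <= spec$tau_upper) 0 else -Inf
    dxc <- (cc - 1) * xcell
    dll <- sum(y[cells] * dxc) - sum(mu[cells] * expm1(dxc))
    if (is.finite(lpr) && log(stats::runif(1L)) < dll + lpr - 2 * s) {
      eta[cells] <<- eta[cells] + dxc
      mu[cells] <<- mu[cells] * exp(dxc)
      list(x = cc * x, tau = tau_new)
    } else list(x = x, tau = tau)
  }
  all_cells <- seq_len(ncell)

  kept <- 0L
  for (it in seq_len(config$iterations)) {
    adapting <- it <= config$burnin
    astep <- if (adapting) min(0.05, 1 / sqrt(it)) else 0

    # alpha: exact conjugate draw (flat prior) on the lambda = exp(alpha) scale
    b_al <- sum(mu) / exp(alpha)
    alpha_new <- log(stats::rgamma(1L, shape = sum_y, rate = b_al))
    d <- alpha_new - alpha
    alpha <- alpha_new
    eta <- eta + d
    mu <- mu * exp(d)

    # beta: per-covariate random walk
    if (has_X) {
      for (k in seq_len(p)) {
        d <- stats::rnorm(1L, 0, sc$beta[k])
        xc <- Xcell[, k]
        dll <- d * syx[k] - sum(mu * expm1(d * xc))
        dpr <- -(spec$fixed_prec / 2) * ((beta[k] + d)^2 - beta[k]^2)
        acc_d["beta"] <- acc_d["beta"] + 1
        if (log(stats::runif(1L)) < dll + dpr) {
          beta[k] <- beta[k] + d
          eta <- eta + d * xc
          mu <- mu * exp(d * xc)
          acc_n["beta"] <- acc_n["beta"] + 1
        }
      }
      if (adapting) {
        r <- acc_n["beta"] / max(acc_d["beta"], 1)
        sc$beta <- sc$beta * exp(astep * (r - target))
      }
    }

    # u: ICAR block, element-wise within color classes
    if (use("spatial")) {
      for (ci in seq_along(classes)) {
        cls <- classes[[ci]]; cc <- cls_cells[[ci]]
        du <- stats::rnorm(length(cls), 0, sc$u)
        mus <- agg_sum(mu[cc], ai[cc], n)[cls]
        m_nb <- vapply(cls, function(i) sum(u[nb[[i]]]), 0) / deg[cls]
        dll <- ysum_a[cls] * du - mus * expm1(du)
        dpr <- -(tau$u * deg[cls] / 2) *
          ((u[cls] + du - m_nb)^2 - (u[cls] - m_nb)^2)
        acc <- log(stats::runif(length(cls))) < dll + dpr
        acc_n["u"] <- acc_n["u"] + sum(acc)
        acc_d["u"] <- acc_d["u"] + length(cls)
        if (any(acc)) {
          du_full <- numeric(n)
          du_full[cls[acc]] <- du[acc]
          u[cls[acc]] <- u[cls[acc]] + du[acc]
          dc <- du_full[ai[cc]]
          eta[cc] <- eta[cc] + dc
          mu[cc] <- mu[cc] * exp(dc)
        }
      }
      if (adapting)
        sc$u <- sc$u * exp(astep * (acc_n["u"] / max(acc_d["u"], 1) - target))
      # recenter (uniform shift preserves eta exactly)
      cshift <- mean(u[nonisl])
      u <- u - cshift
      alpha <- alpha + cshift
      if (it > tau_warmup) {
        tau$u <- draw_tau(icar_df,
                          sum((u[edges[, 1L]] - u[edges[, 2L]])^2))
        sm <- scale_move(u, tau$u, all_cells, u[ai])
        u <- sm$x; tau$u <- sm$tau
      }
    }

    # v: exchangeable heterogeneity, all areas simultaneously
    if (use("het")) {
      dv <- stats::rnorm(n, 0, sc$v)
      mus <- agg_sum(mu, ai, n)
      dll <- ysum_a * dv - mus * expm1(dv)
      dpr <- -(tau$v / 2) * ((v + dv)^2 - v^2)
      acc <- log(stats::runif(n)) < dll + dpr
      acc_n["v"] <- acc_n["v"] + sum(acc); acc_d["v"] <- acc_d["v"] + n
      if (any(acc)) {
        dv[!acc] <- 0
        v <- v + dv
        dc <- dv[ai]
        eta <- eta + dc
        mu <- mu * exp(dc)
      }
      if (adapting)
        sc$v <- sc$v * exp(astep * (acc_n["v"] / max(acc_d["v"], 1) - target))
      if (it > tau_warmup) {
        tau$v <- draw_tau(n, sum(v^2))
        sm <- scale_move(v, tau$v, all_cells, v[ai])
        v <- sm$x; tau$v <- sm$tau
      }
    }

    # t: exchangeable year effects
    if (use("temporal")) {
      dt <- stats::rnorm(J, 0, sc$t)
      mus <- agg_sum(mu, yj, J)
      dll <- ysum_t * dt - mus * expm1(dt)
      dpr <- -(tau$t / 2) * ((tt + dt)^2 - tt^2)
      acc <- log(stats::runif(J)) < dll + dpr
      acc_n["t"] <- acc_n["t"] + sum(acc); acc_d["t"] <- acc_d["t"] + J
      if (any(acc)) {
        dt[!acc] <- 0
        tt <- tt + dt
        dc <- dt[yj]
        eta <- eta + dc
        mu <- mu * exp(dc)
      }
      if (adapting)
        sc$t <- sc$t * exp(astep * (acc_n["t"] / max(acc_d["t"], 1) - target))
      cshift <- mean(tt)
      tt <- tt - cshift
      alpha <- alpha + cshift
      if (it > tau_warmup) {
        tau$t <- draw_tau(J - 1L, sum(tt^2))
        sm <- scale_move(tt, tau$t, all_cells, tt[yj])
        tt <- sm$x; tau$t <- sm$tau
      }
    }

    # psi: space-time interaction, all area-years simultaneously
    if (use("interaction")) {
      dp <- stats::rnorm(n * J, 0, sc$psi)
      mus <- agg_sum(mu, py_idx, n * J)
      dll <- ysum_py * dp - mus * expm1(dp)
      dpr <- -(tau$psi / 2) * ((psi + dp)^2 - psi^2)
      acc <- log(stats::runif(n * J)) < dll + dpr
      acc_n["psi"] <- acc_n["psi"] + sum(acc)
      acc_d["psi"] <- acc_d["psi"] + n * J
      if (any(acc)) {
        dp[!acc] <- 0
        psi <- psi + dp
        dc <- dp[py_idx]
        eta <- eta + dc
        mu <- mu * exp(dc)
      }
      if (adapting)
        sc$psi <- sc$psi *
          exp(astep * (acc_n["psi"] / max(acc_d["psi"], 1) - target))
      if (it > tau_warmup) {
        tau$psi <- draw_tau(n * J, sum(psi^2))
        sm <- scale_move(psi, tau$psi, all_cells, psi[py_idx])
        psi <- sm$x; tau$psi <- sm$tau
      }
    }

    if (use("disparity")) {
      # delta0: random walk on focal cells
      d <- stats::rnorm(1L, 0, sc$delta0)
      dll <- sum_y_foc * d - sum(mu[foc]) * expm1(d)
      dpr <- -(spec$fixed_prec / 2) * ((delta0 + d)^2 - delta0^2)
      acc_d["delta0"] <- acc_d["delta0"] + 1
      if (log(stats::runif(1L)) < dll + dpr) {
        delta0 <- delta0 + d
        eta[foc] <- eta[foc] + d
        mu[foc] <- mu[foc] * exp(d)
        acc_n["delta0"] <- acc_n["delta0"] + 1
      }
      if (adapting)
        sc$delta0 <- sc$delta0 *
          exp(astep * (acc_n["delta0"] / max(acc_d["delta0"], 1) - target))

      # delta deviations (Models 2-3)
      if (model == 2L) {
        dd <- stats::rnorm(n, 0, sc$delta)
        musf <- agg_sum(mu[foc], ai[foc], n)
        dll <- ysum_fa * dd - musf * expm1(dd)
        dpr <- -(tau$delta / 2) * ((delta + dd)^2 - delta^2)
        acc <- log(stats::runif(n)) < dll + dpr
        acc_n["delta"] <- acc_n["delta"] + sum(acc)
        acc_d["delta"] <- acc_d["delta"] + n
        if (any(acc)) {
          dd[!acc] <- 0
          delta <- delta + dd
          dc <- dd[ai[foc]]
          eta[foc] <- eta[foc] + dc
          mu[foc] <- mu[foc] * exp(dc)
        }
        cshift <- mean(delta)
        delta <- delta - cshift
        delta0 <- delta0 + cshift
        if (it > tau_warmup) {
          tau$delta <- draw_tau(n - 1L, sum(delta^2))
          sm <- scale_move(delta, tau$delta, foc, delta[ai[foc]])
          delta <- sm$x; tau$delta <- sm$tau
        }
      } else if (model == 3L) {
        for (ci in seq_along(classes)) {
          cls <- classes[[ci]]; cc <- cls_cells_foc[[ci]]
          dd <- stats::rnorm(length(cls), 0, sc$delta)
          musf <- agg_sum(mu[cc], ai[cc], n)[cls]
          m_nb <- vapply(cls, function(i) sum(delta[nb[[i]]]), 0) / deg[cls]
          dll <- ysum_fa[cls] * dd - musf * expm1(dd)
          dpr <- -(tau$delta * deg[cls] / 2) *
            ((delta[cls] + dd - m_nb)^2 - (delta[cls] - m_nb)^2)
          acc <- log(stats::runif(length(cls))) < dll + dpr
          acc_n["delta"] <- acc_n["delta"] + sum(acc)
          acc_d["delta"] <- acc_d["delta"] + length(cls)
          if (any(acc)) {
            dd_full <- numeric(n)
            dd_full[cls[acc]] <- dd[acc]
            delta[cls[acc]] <- delta[cls[acc]] + dd[acc]
            dc <- dd_full[ai[cc]]
            eta[cc] <- eta[cc] + dc
            mu[cc] <- mu[cc] * exp(dc)
          }
        }
        cshift <- mean(delta[nonisl])
        delta <- delta - cshift
        delta0 <- delta0 + cshift
        if (it > tau_warmup) {
          tau$delta <- draw_tau(icar_df,
                                sum((delta[edges[, 1L]] -
                                       delta[edges[, 2L]])^2))
          sm <- scale_move(delta, tau$delta, foc, delta[ai[foc]])
          delta <- sm$x; tau$delta <- sm$tau
        }
      }
      if (adapting && model >= 2L)
        sc$delta <- sc$delta *
          exp(astep * (acc_n["delta"] / max(acc_d["delta"], 1) - target))
    }

    # periodic exact recompute to cap incremental float drift
    if (it %% 250L == 0L) {
      xb <- if (has_X) as.vector(Xcell %*% beta) else 0
      eta <- alpha + (delta0 + if (model >= 2L) delta[ai] else 0) * g +
        xb + u[ai] + v[ai] + tt[yj] + psi[py_idx]
      mu <- e * exp(eta)
    }

    if (it > config$burnin && (it - config$burnin) %% config$thin == 0L) {
      kept <- kept + 1L
      out$alpha[kept] <- alpha
      out$delta0[kept] <- delta0
      if (p > 0L) out$beta[kept, ] <- beta
      out$t[kept, ] <- tt
      out$u[kept, ] <- u
      out$v[kept, ] <- v
      if (model >= 2L) out$delta[kept, ] <- delta
      out$tau[kept, ] <- unlist(tau)
      if (config$keep_eta) out$eta[kept, ] <- eta
      out$deviance[kept] <- -2 * sum(poisson_loglik(y, mu))
      out$eta_sum <- out$eta_sum + eta
      out$theta_sum <- out$theta_sum + exp(eta)
      out$psi_sum <- out$psi_sum + psi
    }
  }
  out$accept <- ifelse(acc_d > 0, acc_n / acc_d, NA_real_)
  out
}

#' Posterior mean and equal-tailed 95% credible interval
#'
#' @param draws numeric vector of posterior draws (at least 2).
#' @return Named numeric vector `(mean, lo95, hi95)`; the mean always lies
#'   inside the interval.
#' @export
summarize_draws <- function(draws) {
  if (length(draws) < 2L) stop("need at least 2 draws")
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(draws), lo95 = q[1L], hi95 = q[2L])
}

# Tidy summary table over all scalar components of a fit.
fit_summary <- function(fit) {
  rows <- list()
  add <- function(parameter, block, index, draws)
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(parameter = parameter, block = block, index = index,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(summarize_draws(draws))))
  add("alpha", "fixed", NA, fit$draws$alpha)
  if ("disparity" %in% fit$components)
    add("delta0", "fixed", NA, fit$draws$delta0)
  if (!is.null(fit$draws$beta) && ncol(fit$draws$beta) > 0L)
    for (k in seq_len(ncol(fit$draws$beta)))
      add(colnames(fit$draws$beta)[k] %||% paste0("beta", k), "fixed", k,
          fit$draws$beta[, k])
  for (k in colnames(fit$draws$tau))
    add(k, "precision", NA, fit$draws$tau[, k])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || a == "") b else a

#' @export
print.disparity_fit <- function(x, ...) {
  cat(sprintf("disparity_fit: Model %d, %d draws (%d chains), %d cells\n",
              x$spec$model, x$n_draws, x$config$chains, nrow(x$cells)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Disparity coefficient as percent excess risk
#'
#' Transforms a log relative-risk disparity coefficient to the percent
#' increase in risk of the focal group over the reference group:
#' `100 * (exp(delta) - 1)`.
#'
#' @param delta coefficient(s) on the log relative-risk scale.
#' @return Percent excess risk (vectorized).
#' @export
disparity_percent <- function(delta) 100 * (exp(delta) - 1)

#' Model-based fitted SIR surface
#'
#' Posterior mean (and, when cell-level draws were retained, equal-tailed
#' 95% interval) of `exp(log theta)` per cell — the smoothed, model-based
#' standardized incidence ratio, exportable per year for mapping.
#'
#' @param fit a [fit_model()] result.
#' @return data.frame with cell keys and `mean`, `lo95`, `hi95` columns
#'   (intervals `NA` if `keep_eta` was off).
#' @export
fitted_sir <- function(fit) {
  out <- fit$cells
  out$mean <- fit$theta_mean
  if (!is.null(fit$eta_draws)) {
    th <- exp(fit$eta_draws)
    qs <- apply(th, 2L, stats::quantile, c(0.025, 0.975), names = FALSE)
    out$lo95 <- qs[1L, ]; out$hi95 <- qs[2L, ]
  } else {
    out$lo95 <- NA_real_; out$hi95 <- NA_real_
  }
  out
}

#' Per-area disparity relative-risk surface
#'
#' Posterior mean and 95% interval of `exp(delta0 + delta_i)` — the focal
#' group's relative risk multiplier in each area. For Model 1 the statewide
#' `exp(delta0)` is replicated across areas.
#'
#' @param fit a [fit_model()] result (fit with the disparity component).
#' @return data.frame with one row per area: `area_id`, `mean`, `lo95`,
#'   `hi95`.
#' @export
disparity_surface <- function(fit) {
  if (!"disparity" %in% fit$components)
    stop("fit has no disparity component")
  n <- length(fit$areas)
  dmat <- if (fit$spec$model >= 2L)
    exp(fit$draws$delta0 + fit$draws$delta)
  else exp(matrix(fit$draws$delta0, nrow = fit$n_draws, ncol = n))
  qs <- apply(dmat, 2L, stats::quantile, c(0.025, 0.975), names = FALSE)
  data.frame(area_id = fit$areas, mean = colMeans(dmat),
             lo95 = qs[1L, ], hi95 = qs[2L, ], stringsAsFactors = FALSE)
}

#' Export fit summaries as a tidy table
#'
#' @param fit a [fit_model()] result.
#' @param file optional CSV path.
#' @return The summary data.frame (parameter, block, index, mean, lo95,
#'   hi95), invisibly if written.
#' @export
fit_summary_table <- function(fit, file = NULL) {
  s <- fit$summary
  if (!is.null(file)) {
    utils::write.csv(s, file, row.names = FALSE)
    return(invisible(s))
  }
  s
}
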