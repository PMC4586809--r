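#' Configuration for the synthetic panel generator
#'
#' Generates stratified areal incidence panels from the same hierarchical
#' model the package fits, with every generating value recorded, so that
#' parameter recovery, model selection and calibration can be tested without
#' restricted registry data. Defaults emulate a Texas-registry-scale panel:
#' 254 areas by 9 years by 2 ethnic groups per cancer type, county
#' populations spanning several orders of magnitude with many areas holding
#' small focal-group populations (which yields realistic focal zero-count
#' sparsity), and hyperparameter magnitudes typical of fitted disease-mapping
#' models of this kind.
#'
#' @param n_areas,n_years panel dimensions.
#' @param graph `"grid"` (queen-contiguity lattice trimmed to `n_areas`) or
#'   `"random_planar"` (Delaunay triangulation of uniform random points).
#' @param pop_meanlog,pop_sdlog log-normal law for total area population
#'   (constant over years).
#' @param focal_share_shape1,focal_share_shape2 Beta law for the focal
#'   group's population share per area.
#' @param model which model generates the disparity deviations: 1 (none),
#'   2 (exchangeable), 3 (ICAR).
#' @param cancers named list of per-stratum truths; each element is a list
#'   with `rate_reference`, `rate_focal` (cases per person-year), `alpha`,
#'   `delta0`, `beta` (length 4: poverty, hospitals_per10k, construction,
#'   metro — applied to z-scored covariates), and precisions `tau_u`,
#'   `tau_v`, `tau_t`, `tau_psi`, `tau_delta`.
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(n_areas = 254L, n_years = 9L,
                       graph = c("grid", "random_planar"),
                       pop_meanlog = log(20000), pop_sdlog = 1.6,
                       focal_share_shape1 = 1.2, focal_share_shape2 = 3.8,
                       model = 3L,
                       cancers = list(
                         digestive = list(
                           rate_reference = 9.5e-4, rate_focal = 4.6e-4,
                           alpha = -0.10, delta0 = 0.15,
                           beta = c(poverty = -0.033,
                                    hospitals_per10k = -0.016,
                                    construction = -0.001, metro = 0.021),
                           tau_u = 429, tau_v = 93, tau_t = 478,
                           tau_psi = 297, tau_delta = 16),
                         respiratory = list(
                           rate_reference = 8.8e-4, rate_focal = 2.9e-4,
                           alpha = -0.074, delta0 = 0.15,
                           beta = c(poverty = 0.001,
                                    hospitals_per10k = -0.007,
                                    construction = 0.050, metro = 0.054),
                           tau_u = 923, tau_v = 21, tau_t = 1539,
                           tau_psi = 289, tau_delta = 18))) {
  graph <- match.arg(graph)
  stopifnot(n_areas >= 2L, n_years >= 1L, model %in% 1:3,
            pop_sdlog > 0, focal_share_shape1 > 0, focal_share_shape2 > 0)
  for (tr in cancers) {
    taus <- unlist(tr[c("tau_u", "tau_v", "tau_t", "tau_psi", "tau_delta")])
    stopifnot(all(taus > 0), tr$rate_reference > 0, tr$rate_focal > 0)
  }
  structure(list(n_areas = as.integer(n_areas), n_years = as.integer(n_years),
                 graph = graph, pop_meanlog = pop_meanlog,
                 pop_sdlog = pop_sdlog,
                 focal_share_shape1 = focal_share_shape1,
                 focal_share_shape2 = focal_share_shape2,
                 model = as.integer(model), cancers = cancers),
            class = "gen_config")
}

#' Generate an adjacency graph for synthetic panels
#'
#' `"grid"` lays areas row-major on a near-square lattice with queen
#' contiguity; `"random_planar"` triangulates uniform random points
#' (Delaunay), giving a connected planar graph with mean degree close to six.
#' Disconnected draws are regenerated up to a retry cap.
#'
#' @param n_areas number of areas (>= 2).
#' @param kind `"grid"` or `"random_planar"`.
#' @param seed integer seed (used by `"random_planar"`).
#' @return A connected [adjacency_graph()] with areas `A001 ...`.
#' @export
make_graph <- function(n_areas, kind = c("grid", "random_planar"), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_areas >= 2L)
  ids <- sprintf("A%03d", seq_len(n_areas))
  if (kind == "grid") {
    nc <- ceiling(sqrt(n_areas))
    row <- (seq_len(n_areas) - 1L) %/% nc
    col <- (seq_len(n_areas) - 1L) %% nc
    pairs <- utils::combn(n_areas, 2L)
    adj <- abs(row[pairs[1L, ]] - row[pairs[2L, ]]) <= 1L &
      abs(col[pairs[1L, ]] - col[pairs[2L, ]]) <= 1L
    g <- adjacency_graph(cbind(ids[pairs[1L, adj]], ids[pairs[2L, adj]]),
                         areas = ids)
  } else {
    set.seed(seed)
    for (try in 1:5) {
      pts <- cbind(stats::runif(n_areas), stats::runif(n_areas))
      edg <- delaunay_edges(pts)
      g <- adjacency_graph(cbind(ids[edg[, 1L]], ids[edg[, 2L]]),
                           areas = ids)
      if (max(graph_components(g)) == 1L) break
      g <- NULL
    }
    if (is.null(g)) stop("failed to generate a connected planar graph")
  }
  if (max(graph_components(g)) != 1L) stop("generated graph is disconnected")
  g
}

# Delaunay triangulation by Bowyer-Watson insertion; returns unique i<j
# vertex-index edge pairs. O(n^2), adequate for panel-sized graphs.
delaunay_edges <- function(pts) {
  n <- nrow(pts)
  M <- 50
  P <- rbind(pts, c(-M, -M), c(2 * M, -M), c(0.5, 2 * M))
  sup <- n + 1:3
  circum <- function(tri) {
    a <- P[tri[1L], ]; b <- P[tri[2L], ]; ck <- P[tri[3L], ]
    d <- 2 * (a[1L] * (b[2L] - ck[2L]) + b[1L] * (ck[2L] - a[2L]) +
                ck[1L] * (a[2L] - b[2L]))
    aa <- sum(a^2); bb <- sum(b^2); cc <- sum(ck^2)
    ux <- (aa * (b[2L] - ck[2L]) + bb * (ck[2L] - a[2L]) +
             cc * (a[2L] - b[2L])) / d
    uy <- (aa * (ck[1L] - b[1L]) + bb * (a[1L] - ck[1L]) +
             cc * (b[1L] - a[1L])) / d
    c(ux, uy, (ux - a[1L])^2 + (uy - a[2L])^2)
  }
  tris <- matrix(sup, nrow = 1L)
  cc <- matrix(circum(sup), nrow = 1L)
  for (v in seq_len(n)) {
    bad <- (P[v, 1L] - cc[, 1L])^2 + (P[v, 2L] - cc[, 2L])^2 < cc[, 3L]
    # boundary = edges of bad triangles that appear exactly once
    be <- rbind(tris[bad, c(1L, 2L), drop = FALSE],
                tris[bad, c(2L, 3L), drop = FALSE],
                tris[bad, c(1L, 3L), drop = FALSE])
    be <- t(apply(be, 1L, sort))
    key <- paste(be[, 1L], be[, 2L])
    once <- names(which(table(key) == 1L))
    be <- be[key %in% once & !duplicated(key), , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    if (nrow(be) > 0L) {
      newt <- cbind(be, v)
      tris <- rbind(tris, newt)
      cc <- rbind(cc, t(apply(newt, 1L, circum)))
    }
  }
  keep <- !(tris[, 1L] %in% sup | tris[, 2L] %in% sup | tris[, 3L] %in% sup)
  tris <- tris[keep, , drop = FALSE]
  e <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

# Draw from the intrinsic CAR distribution with precision tau * (D - W),
# restricted to the sum-to-zero subspace: scale the eigenvectors of (D - W)
# with positive eigenvalues by 1/sqrt(tau * lambda). Isolated areas sit in
# the null space and come back exactly zero.
ricar <- function(graph, tau) {
  n <- length(graph$areas)
  Q <- diag(graph$n, n)
  e <- graph$edges
  if (nrow(e) > 0L) {
    Q[e] <- Q[e] - 1
    Q[e[, c(2L, 1L), drop = FALSE]] <- Q[cbind(e[, 2L], e[, 1L])] - 1
  }
  eig <- eigen(Q, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  if (!any(pos)) return(numeric(n))
  z <- stats::rnorm(sum(pos))
  as.vector(eig$vectors[, pos, drop = FALSE] %*%
              (z / sqrt(tau * eig$values[pos])))
}

#' Simulate the generating truth for a synthetic panel
#'
#' Draws every random-effect vector from its prior at the configured truth
#' precisions — `u` from the constrained ICAR, `v`/`t`/`psi` exchangeable
#' normal, disparity deviations per the configured model — plus per-area
#' covariates. Constrained blocks are recentered exactly.
#'
#' @param config a [gen_config()].
#' @param graph an [adjacency_graph()] with `config$n_areas` areas.
#' @param seed integer seed.
#' @return An object of class `synthetic_truth`: per-cancer parameter values
#'   and effect vectors, plus the covariate table.
#' @export
simulate_truth <- function(config, graph, seed = 1L) {
  stopifnot(inherits(config, "gen_config"),
            length(graph$areas) == config$n_areas)
  set.seed(seed)
  n <- config$n_areas; J <- config$n_years
  covariates <- data.frame(
    area_id = graph$areas,
    poverty = stats::rbeta(n, 5, 23),
    hospitals_per10k = ifelse(stats::runif(n) < 0.26, 0,
                              stats::rgamma(n, shape = 2, scale = 0.45)),
    construction = stats::rbeta(n, 8, 90),
    metro = stats::rbinom(n, 1L, 0.30),
    stringsAsFactors = FALSE)
  strata <- lapply(config$cancers, function(tr) {
    u <- ricar(graph, tr$tau_u)
    u <- u - mean(u)
    v <- stats::rnorm(n, 0, 1 / sqrt(tr$tau_v))
    tt <- stats::rnorm(J, 0, 1 / sqrt(tr$tau_t))
    tt <- tt - mean(tt)
    psi <- matrix(stats::rnorm(n * J, 0, 1 / sqrt(tr$tau_psi)), n, J)
    delta <- switch(config$model,
                    NULL,
                    { d <- stats::rnorm(n, 0, 1 / sqrt(tr$tau_delta))
                      d - mean(d) },
                    { d <- ricar(graph, tr$tau_delta)
                      d - mean(d) })
    parameter_state(alpha = tr$alpha, delta0 = tr$delta0, delta = delta,
                    beta = tr$beta, u = u, v = v, t = tt, psi = psi,
                    tau = list(u = tr$tau_u, v = tr$tau_v, t = tr$tau_t,
                               psi = tr$tau_psi,
                               delta = if (config$model >= 2L) tr$tau_delta))
  })
  structure(list(strata = strata, covariates = covariates,
                 model = config$model, seed = seed),
            class = "synthetic_truth")
}

#' Simulate an areal panel from a generating truth
#'
#' Populations are drawn from the configured log-normal law (constant over
#' years); the focal group's share from the Beta law; expected counts apply
#' the configured group reference rates to the simulated populations
#' (`e = n * r_k`, the indirect-standardization construction with the
#' generator's statewide rates taken as known); counts are
#' `y ~ Poisson(e * theta_true)` cell-wise, with `theta_true` from the truth
#' state evaluated on z-scored covariates.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the [gen_config()] used for the truth.
#' @param seed integer seed.
#' @return list with `panel` (an [areal_panel()]), `expected` (aligned
#'   [expected_counts()]), and `theta` (the true relative risks, aligned).
#' @export
simulate_panel <- function(truth, config, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  n <- config$n_areas; J <- config$n_years
  areas <- truth$covariates$area_id
  pop <- round(stats::rlnorm(n, config$pop_meanlog, config$pop_sdlog))
  pop <- pmax(pop, 100)
  share <- stats::rbeta(n, config$focal_share_shape1,
                        config$focal_share_shape2)
  n_focal <- round(pop * share)
  n_ref <- pop - n_focal

  Xr <- as.matrix(truth$covariates[-1L])
  mu <- colMeans(Xr); s <- apply(Xr, 2L, stats::sd); s[s == 0] <- 1
  X <- sweep(sweep(Xr, 2L, mu), 2L, s, "/")

  grid <- expand.grid(group = 0:1, year = seq_len(J) - 1L,
                      area = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(names(config$cancers), function(cn) {
    tr <- config$cancers[[cn]]
    st <- truth$strata[[cn]]
    eta <- linear_predictor(
      st, data.frame(area = grid$area, year = grid$year + 1L,
                     eth = grid$group), X = X)
    theta <- exp(eta)
    nn <- ifelse(grid$group == 1L, n_focal[grid$area], n_ref[grid$area])
    r <- ifelse(grid$group == 1L, tr$rate_focal, tr$rate_reference)
    e <- nn * r
    data.frame(area_id = areas[grid$area], year = grid$year,
               group = grid$group, cancer = cn,
               count = stats::rpois(length(e), e * theta), population = nn,
               theta = theta, stringsAsFactors = FALSE)
  })
  dat <- do.call(rbind, rows)
  panel <- areal_panel(dat[c("area_id", "year", "group", "cancer", "count",
                             "population")],
                       covariates = truth$covariates)
  # generator rates are the known statewide reference rates
  rates <- do.call(rbind, lapply(names(config$cancers), function(cn)
    data.frame(cancer = cn, group = 0:1, cases = NA_real_,
               person_years = NA_real_,
               rate = c(config$cancers[[cn]]$rate_reference,
                        config$cancers[[cn]]$rate_focal),
               stringsAsFactors = FALSE)))
  expected <- expected_counts(panel, rates)
  # align theta to the (reordered) panel
  key_dat <- paste(dat$cancer, dat$area_id, dat$year, dat$group)
  key_pan <- paste(panel$cancer, panel$area_id, panel$year, panel$group)
  list(panel = panel, expected = expected,
       theta = dat$theta[match(key_pan, key_dat)])
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: graph, truth and panel in one call with sub-seeds
#' derived from `seed`.
#'
#' @param config a [gen_config()].
#' @param seed integer seed.
#' @return list with `graph`, `truth`, `panel`, `expected`, `theta`.
#' @export
simulate_dataset <- function(config = gen_config(), seed = 1L) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  graph <- make_graph(config$n_areas, config$graph, seed = sub[1L])
  truth <- simulate_truth(config, graph, seed = sub[2L])
  sim <- simulate_panel(truth, config, seed = sub[3L])
  c(list(graph = graph, truth = truth), sim)
}

#' Fraction of focal-group zero-count area-years
#'
#' The sparsity summary used to check that synthetic panels emulate
#' registry-like data, where a substantial share of small areas record no
#' focal-group cases in a given year.
#'
#' @param panel an [areal_panel()].
#' @param by_cancer if TRUE (default), one fraction per cancer type.
#' @return Named numeric vector of zero fractions.
#' @export
focal_zero_fraction <- function(panel, by_cancer = TRUE) {
  f <- panel[panel$group == 1L, , drop = FALSE]
  if (by_cancer) {
    vapply(split(f$count, f$cancer), function(v) mean(v == 0L), 0)
  } else c(all = mean(f$count == 0L))
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the panel CSV, covariates CSV, adjacency edge list and a YAML truth
#' record — the inputs the fitting pipeline consumes.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(panel = file.path(dir, "panel.csv"),
             covariates = file.path(dir, "covariates.csv"),
             adjacency = file.path(dir, "adjacency.txt"),
             truth = file.path(dir, "truth.yaml"))
  write_panel(sim$panel, paths["panel"], paths["covariates"])
  write_adjacency(sim$graph, paths["adjacency"])
  tr <- lapply(sim$truth$strata, function(st)
    lapply(unclass(st), function(x) if (is.matrix(x)) as.vector(x) else x))
  yaml::write_yaml(list(model = sim$truth$model, seed = sim$truth$seed,
                        strata = tr), paths["truth"])
  invisible(paths)
}
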