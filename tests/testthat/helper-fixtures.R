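# Shared fixtures built in code.

# Small complete panel: n areas x J years x 2 groups, one cancer type.
tiny_panel <- function(n = 4L, J = 2L, counts = NULL, pops = 1000,
                       cancer = "digestive", covariates = TRUE) {
  grid <- expand.grid(group = 0:1, year = seq_len(J) - 1L,
                      area_id = sprintf("A%03d", seq_len(n)),
                      cancer = cancer, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$population <- rep_len(pops, nrow(grid))
  grid$count <- if (is.null(counts)) rep_len(5L, nrow(grid))
                else rep_len(counts, nrow(grid))
  covs <- if (covariates)
    data.frame(area_id = sprintf("A%03d", seq_len(n)),
               poverty = seq(0.1, 0.3, length.out = n),
               hospitals_per10k = seq(0, 1, length.out = n),
               construction = rep(0.08, n),
               metro = rep(c(0L, 1L), length.out = n))
  areal_panel(grid[c("area_id", "year", "group", "cancer", "count",
                     "population")], covariates = covs)
}

# Path graph over the panel's areas.
path_graph <- function(n = 4L) {
  ids <- sprintf("A%03d", seq_len(n))
  adjacency_graph(cbind(ids[-n], ids[-1L]), areas = ids)
}

# A ready (panel, expected, graph) triple from the synthetic generator,
# small enough for fast fits.
small_sim <- function(seed = 1L, n_areas = 25L, n_years = 3L) {
  cfg <- gen_config(n_areas = n_areas, n_years = n_years)
  sim <- simulate_dataset(cfg, seed = seed)
  pan <- panel_stratum(sim$panel, "digestive")
  list(config = cfg, sim = sim, panel = pan,
       expected = expected_counts(pan, attr(sim$expected, "rates")),
       graph = sim$graph)
}

# Grid of unit-square polygons (m rows x k cols) as a named ring list.
unit_square_grid <- function(m, k) {
  polys <- list()
  for (r in seq_len(m)) for (c in seq_len(k)) {
    x <- c - 1; y <- r - 1
    ring <- rbind(c(x, y), c(x + 1, y), c(x + 1, y + 1), c(x, y + 1),
                  c(x, y))
    polys[[sprintf("g%d_%d", r, c)]] <- list(ring)
  }
  polys
}

# Random parameter state matched to a graph, for log-density oracles.
random_state <- function(graph, J = 3L, p = 0L, model = 3L, seed = 1L) {
  set.seed(seed)
  n <- length(graph$areas)
  parameter_state(
    alpha = rnorm(1, 0, 0.2), delta0 = rnorm(1, 0, 0.1),
    delta = if (model >= 2L) rnorm(n, 0, 0.1),
    beta = if (p > 0L) rnorm(p, 0, 0.05) else numeric(0),
    u = rnorm(n, 0, 0.2), v = rnorm(n, 0, 0.1), t = rnorm(J, 0, 0.05),
    psi = matrix(rnorm(n * J, 0, 0.05), n, J),
    tau = list(u = 400, v = 90, t = 500, psi = 300,
               delta = if (model >= 2L) 16))
}

# All connected labelled graphs on n nodes (edge-subset enumeration).
connected_graphs <- function(n) {
  ids <- sprintf("A%03d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  m <- ncol(pairs)
  out <- list()
  for (mask in seq_len(2^m - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    g <- adjacency_graph(cbind(ids[pairs[1L, sel]], ids[pairs[2L, sel]]),
                         areas = ids)
    if (max(arealdisp:::graph_components(g)) == 1L)
      out[[length(out) + 1L]] <- g
  }
  out
}
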