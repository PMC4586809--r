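#' Construct a symmetric adjacency graph over areas
#'
#' The neighbour structure drives the intrinsic CAR (ICAR) priors: each
#' area's spatial effect is conditionally centred on the mean of its
#' neighbours with conditional precision proportional to its neighbour count.
#'
#' @param edges two-column matrix or data.frame of area-id pairs. Edges are
#'   symmetrized; self-loops are dropped with a warning.
#' @param areas character vector of all area ids (isolated areas permitted).
#'   Defaults to the ids present in `edges`.
#' @return An object of class `adjacency_graph`: list with `areas`, `nb`
#'   (list of integer neighbour indices per area), `n` (neighbour counts),
#'   and `edges` (unique i<j integer index pairs).
#' @export
adjacency_graph <- function(edges, areas = NULL) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  a <- as.character(edges[, 1L]); b <- as.character(edges[, 2L])
  if (is.null(areas)) areas <- sort(unique(c(a, b)))
  areas <- as.character(areas)
  if (anyDuplicated(areas)) stop("duplicate area ids")
  unknown <- setdiff(unique(c(a, b)), areas)
  if (length(unknown) > 0L)
    stop("edge references unknown area id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    a <- a[!self]; b <- b[!self]
  }
  ia <- match(a, areas); ib <- match(b, areas)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  keep <- !duplicated(paste(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  n_area <- length(areas)
  nb <- vector("list", n_area)
  for (i in seq_len(n_area)) nb[[i]] <- integer(0)
  for (e in seq_along(lo)) {
    nb[[lo[e]]] <- c(nb[[lo[e]]], hi[e])
    nb[[hi[e]]] <- c(nb[[hi[e]]], lo[e])
  }
  nb <- lapply(nb, function(v) sort(unique(v)))
  structure(list(areas = areas, nb = nb,
                 n = vapply(nb, length, integer(1)),
                 edges = cbind(i = lo, j = hi)),
            class = "adjacency_graph")
}

#' Read an adjacency graph from a whitespace-separated edge list
#'
#' @param file path: two area ids per line. The listing may be asymmetric;
#'   the graph is symmetrized.
#' @param areas optional full area-id set (to retain isolated areas and to
#'   validate ids against a panel).
#' @return An [adjacency_graph()].
#' @export
read_adjacency <- function(file, areas = NULL) {
  tab <- utils::read.table(file, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) != 2L) stop("edge list must have exactly two columns")
  adjacency_graph(as.matrix(tab), areas = areas)
}

#' Write an adjacency graph as an edge list
#'
#' @param graph an [adjacency_graph()].
#' @param file output path; one `i j` pair per line (i < j).
#' @return Invisibly, `file`.
#' @export
write_adjacency <- function(graph, file) {
  e <- graph$edges
  utils::write.table(
    data.frame(a = graph$areas[e[, 1L]], b = graph$areas[e[, 2L]]),
    file, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d areas, %d edges, degree %d-%d (mean %.2f)\n",
              length(x$areas), nrow(x$edges), min(x$n), max(x$n), mean(x$n)))
  iso <- sum(x$n == 0L)
  if (iso > 0L) cat("  ", iso, "isolated area(s)\n")
  invisible(x)
}

#' Build a contiguity graph from polygon geometries
#'
#' Queen contiguity links any two polygons sharing at least one boundary
#' point; rook contiguity requires a shared boundary segment of positive
#' length. Coordinates are snapped to a regular grid before comparison, so
#' shared boundaries must have exactly coincident vertices after snapping
#' (the usual situation for administrative boundary files).
#'
#' @param geo either a path to a GeoJSON FeatureCollection whose features
#'   carry an `area_id` property, or a named list of polygons, each a list of
#'   rings, each ring an n x 2 coordinate matrix.
#' @param rule `"queen"` (default) or `"rook"`.
#' @param snap snapping grid size for coordinate comparison.
#' @return An [adjacency_graph()]. Isolated polygons are allowed and listed
#'   in a warning.
#' @export
build_contiguity <- function(geo, rule = c("queen", "rook"), snap = 1e-9) {
  rule <- match.arg(rule)
  polys <- if (is.character(geo)) read_geojson_polygons(geo) else geo
  if (length(polys) == 0L) stop("no polygons supplied")
  ids <- names(polys)
  if (is.null(ids) || any(ids == "")) stop("polygons must be named by area_id")

  snap_key <- function(coords) {
    if (!is.matrix(coords) || ncol(coords) != 2L || nrow(coords) < 3L)
      stop("degenerate ring: need an n x 2 matrix with at least 3 vertices")
    if (any(!is.finite(coords))) stop("non-finite coordinates in geometry")
    paste(round(coords[, 1L] / snap), round(coords[, 2L] / snap))
  }
  # Per polygon: the set of snapped vertices and of undirected boundary edges.
  verts <- vector("list", length(polys))
  bedges <- vector("list", length(polys))
  for (p in seq_along(polys)) {
    rings <- polys[[p]]
    vk <- character(0); ek <- character(0)
    for (ring in rings) {
      k <- snap_key(ring)
      if (k[1L] == k[length(k)]) k <- k[-length(k)]  # drop closing vertex
      if (length(k) < 3L) stop("degenerate ring in polygon ", ids[p])
      nxt <- c(k[-1L], k[1L])
      ek <- c(ek, paste(pmin(k, nxt), pmax(k, nxt), sep = "|"))
      vk <- c(vk, k)
    }
    verts[[p]] <- unique(vk)
    bedges[[p]] <- unique(ek)
  }

  # Invert vertex->polygons; only polygons sharing a vertex can be neighbors
  # under either rule (rook edges have shared endpoints).
  vert_tab <- data.frame(key = unlist(verts),
                         poly = rep(seq_along(polys),
                                    lengths(verts)))
  cand <- unique(do.call(rbind, lapply(
    split(vert_tab$poly, vert_tab$key), function(ps) {
      ps <- unique(ps)
      if (length(ps) < 2L) return(NULL)
      t(utils::combn(sort(ps), 2L))
    })))
  out <- NULL
  if (!is.null(cand) && nrow(cand) > 0L) {
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      keep[r] <- if (rule == "queen") TRUE
                 else length(intersect(bedges[[i]], bedges[[j]])) > 0L
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) > 0L)
      out <- cbind(ids[cand[, 1L]], ids[cand[, 2L]])
  }
  g <- adjacency_graph(if (is.null(out)) matrix(character(0), ncol = 2L)
                       else out, areas = sort(ids))
  iso <- g$areas[g$n == 0L]
  if (length(iso) > 0L)
    warning("isolated polygon(s): ", paste(iso, collapse = ", "))
  g
}

# Parse a GeoJSON FeatureCollection of (Multi)Polygons into a named list of
# polygons (list of rings, each an n x 2 matrix). Coordinates pass through
# untouched; no CRS handling.
read_geojson_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  polys <- list()
  for (f in gj$features) {
    id <- f$properties$area_id
    if (is.null(id)) stop("feature without an area_id property")
    geom <- f$geometry
    if (is.null(geom) || is.null(geom$type))
      stop("feature ", id, " has no geometry")
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly)
        lapply(poly, ring_mat)), recursive = FALSE),
      stop("unsupported geometry type: ", geom$type))
    polys[[as.character(id)]] <- rings
  }
  polys
}

# Connected components (integer labels, 1-based) -- used for the ICAR rank.
graph_components <- function(graph) {
  n <- length(graph$areas)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, graph$nb[[v]][comp[graph$nb[[v]]] == 0L])
    }
  }
  comp
}

# Greedy proper coloring: areas in the same color class have no edge between
# them, so their ICAR full conditionals are mutually independent and can be
# updated simultaneously.
graph_coloring <- function(graph) {
  n <- length(graph$areas)
  col <- integer(n)
  for (v in order(graph$n, decreasing = TRUE)) {
    used <- col[graph$nb[[v]]]
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    col[v] <- c0
  }
  col
}

# Bind a graph to a panel: area sets must match exactly.
check_graph_panel <- function(graph, panel) {
  pa <- attr(panel, "areas")
  if (!identical(sort(graph$areas), sort(pa)))
    stop("graph areas do not match panel areas")
  invisible(TRUE)
}
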