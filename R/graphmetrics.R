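#' @importFrom igraph graph_from_adjacency_matrix
as_igraph <- function(net) {
  stopifnot(inherits(net, "fc_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Nodal degree
#'
#' Number of functional connections (edges) each region participates in —
#' equivalently, the row sums of the adjacency matrix.
#'
#' @param net an `fc_network`.
#' @return named integer vector, one entry per region.
#' @export
node_degree <- function(net) {
  d <- igraph::degree(as_igraph(net))
  stats::setNames(as.integer(d), net$regions)
}

#' Network density
#'
#' Realized edges over possible edges, `2E / (N (N - 1))`.
#'
#' @param net an `fc_network` with at least 2 regions.
#' @return a fraction in `[0, 1]`.
#' @export
network_density <- function(net) {
  if (length(net$regions) < 2L) stop("need >= 2 regions", call. = FALSE)
  igraph::edge_density(as_igraph(net))
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' disconnected pairs contributing 0 (their distance is infinite). Bounded in
#' `[0, 1]`; handles disconnected networks natively, which makes it the
#' preferred whole-network measure when comparing across thresholds that
#' fragment the graph.
#'
#' @param net an `fc_network` with at least 2 regions.
#' @return a value in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  if (length(net$regions) < 2L) stop("need >= 2 regions", call. = FALSE)
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0L) return(0)
  igraph::global_efficiency(g)
}

#' Local clustering coefficient
#'
#' Per region: triangles through the region divided by `k (k - 1) / 2`
#' possible neighbor pairs; defined as 0 for degree < 2 so the vector stays
#' alignable across thresholds.
#'
#' @param net an `fc_network`.
#' @return named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  cc <- igraph::transitivity(as_igraph(net), type = "local",
                             isolates = "zero")
  stats::setNames(cc, net$regions)
}

#' Local efficiency
#'
#' Per region, the [global_efficiency()] of the subgraph induced by the
#' region's neighbors (the Latora-Marchiori convention: paths are confined to
#' the neighborhood, so the measure captures fault tolerance of the local
#' circuit if the region itself were removed); 0 for degree < 2. Note that
#' some toolboxes instead let neighbor-to-neighbor paths traverse the rest of
#' the graph, which yields systematically larger values; the confined
#' definition is used here.
#'
#' @param net an `fc_network`.
#' @return named numeric vector in `[0, 1]`.
#' @export
local_efficiency <- function(net) {
  g <- as_igraph(net)
  adj <- net$adjacency
  le <- vapply(seq_along(net$regions), function(v) {
    nb <- which(adj[v, ] == 1L)
    if (length(nb) < 2L) return(0)
    igraph::global_efficiency(igraph::induced_subgraph(g, nb))
  }, numeric(1))
  le[is.nan(le)] <- 0  # edgeless neighborhood subgraphs
  stats::setNames(le, net$regions)
}

#' Normalized betweenness centrality
#'
#' Fraction of shortest paths between other region pairs that pass through
#' each region (geodesic ties split evenly), normalized by
#' `(N - 1)(N - 2) / 2` so values are comparable across equal-sized networks.
#'
#' @param net an `fc_network`.
#' @return named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(net) {
  b <- igraph::betweenness(as_igraph(net), directed = FALSE,
                           normalized = TRUE)
  stats::setNames(b, net$regions)
}

#' Characteristic path length
#'
#' Mean unweighted shortest-path length over connected (mutually reachable)
#' node pairs. Disconnected pairs are excluded rather than given an arbitrary
#' finite distance; the companion quantity `component_coverage` in
#' [network_metrics()] reports how much of the node set the largest component
#' spans, so path length is never read without knowing how much of the
#' network it describes.
#'
#' @param net an `fc_network`.
#' @return mean geodesic distance; `NaN` when the network has no edges.
#' @export
char_path_length <- function(net) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0L) return(NaN)
  igraph::mean_distance(g, unconnected = TRUE)
}

largest_component <- function(g) {
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
}

#' Small-world coefficient sigma
#'
#' `sigma = (C / <C_rand>) / (L / <L_rand>)`, where `C` is the mean local
#' clustering coefficient and `L` the characteristic path length of the
#' largest connected component, and the null averages are taken over
#' `n_null` random graphs. `sigma > 1` indicates small-world-like topology
#' (more clustered than random at comparable path length), the organization
#' expected of brain networks.
#'
#' @param net an `fc_network`; the comparison runs on its largest connected
#'   component.
#' @param n_null number of null graphs (`>= 1`).
#' @param null_model `"er_matched"`: Erdos-Renyi G(N, E) with the component's
#'   node and edge counts; `"degree_preserving"`: Maslov-Sneppen edge
#'   rewiring of the component itself, preserving the degree sequence.
#' @param seed integer seed; the null ensemble is deterministic given it.
#' @param n_swaps rewiring trials per degree-preserving null (default
#'   `10 * E`).
#' @return a single numeric sigma.
#' @export
small_world_sigma <- function(net, n_null = 100,
                              null_model = c("er_matched", "degree_preserving"),
                              seed = 1L, n_swaps = NULL) {
  null_model <- match.arg(null_model)
  if (n_null < 1) stop("`n_null` must be >= 1", call. = FALSE)
  g <- largest_component(as_igraph(net))
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  if (nv < 3L || ne < 2L) {
    stop("largest component too small for a small-world comparison", call. = FALSE)
  }
  C <- mean(igraph::transitivity(g, type = "local", isolates = "zero"))
  L <- igraph::mean_distance(g, unconnected = TRUE)
  if (is.null(n_swaps)) n_swaps <- 10L * ne
  nulls <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_null), function(i) {
      gn <- switch(null_model,
                   er_matched = igraph::sample_gnm(nv, ne),
                   degree_preserving = igraph::rewire(
                     g, igraph::keeping_degseq(niter = n_swaps)))
      c(C = mean(igraph::transitivity(gn, type = "local", isolates = "zero")),
        L = igraph::mean_distance(gn, unconnected = TRUE))
    })
  })
  C_rand <- mean(vapply(nulls, `[[`, numeric(1), "C"))
  L_rand <- mean(vapply(nulls, `[[`, numeric(1), "L"))
  if (!is.finite(C_rand) || C_rand == 0) {
    stop("undefined sigma: the null ensemble has zero mean clustering",
         call. = FALSE)
  }
  (C / C_rand) / (L / L_rand)
}

#' All graph metrics of a network
#'
#' Convenience bundle of the nodal and global measures used to characterize
#' IEG-based functional connectivity networks.
#'
#' @param net an `fc_network`.
#' @param sigma compute [small_world_sigma()] as well (default `FALSE`; it is
#'   the one stochastic and comparatively slow member of the report).
#' @param ... passed to [small_world_sigma()] when `sigma = TRUE`.
#' @return a `metrics_report`: list with per-region vectors `degree`,
#'   `clustering`, `local_efficiency`, `betweenness`; global scalars
#'   `density`, `global_efficiency`, `mean_clustering`, `char_path_length`,
#'   `component_coverage` (fraction of regions in the largest connected
#'   component) and, optionally, `small_world_sigma`.
#' @export
network_metrics <- function(net, sigma = FALSE, ...) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  rep <- list(
    regions = net$regions,
    degree = node_degree(net),
    clustering = clustering_coefficient(net),
    local_efficiency = local_efficiency(net),
    betweenness = betweenness_centrality(net),
    density = network_density(net),
    global_efficiency = global_efficiency(net),
    mean_clustering = mean(clustering_coefficient(net)),
    char_path_length = char_path_length(net),
    component_coverage = max(comp$csize) / length(net$regions)
  )
  if (isTRUE(sigma)) {
    rep$small_world_sigma <- small_world_sigma(net, ...)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", length(x$regions), " regions\n", sep = "")
  cat(sprintf("  density %.3f | global efficiency %.3f | mean clustering %.3f\n",
              x$density, x$global_efficiency, x$mean_clustering))
  cat(sprintf("  char path length %.3f over largest component covering %.0f%% of regions\n",
              x$char_path_length, 100 * x$component_coverage))
  if (!is.null(x$small_world_sigma)) {
    cat(sprintf("  small-world sigma %.3f\n", x$small_world_sigma))
  }
  invisible(x)
}

#' Tidy per-region metrics table
#'
#' @param report a [network_metrics()] report.
#' @return data.frame with one row per region and columns `region`, `degree`,
#'   `clustering`, `local_efficiency`, `betweenness`.
#' @export
metrics_table <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  data.frame(region = report$regions,
             degree = unname(report$degree),
             clustering = unname(report$clustering),
             local_efficiency = unname(report$local_efficiency),
             betweenness = unname(report$betweenness),
             stringsAsFactors = FALSE)
}
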