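#' Per-node clustering coefficient
#'
#' Triangles through the node divided by connected triples centred on it,
#' \eqn{c = N_\triangle / N_3} with \eqn{N_3 = k(k-1)/2}.  Nodes of degree
#' below 2 centre no triples and get `c = 0` (a convention, not `NA`, so
#' community means stay defined).  Self-loops are ignored.
#'
#' @param net An `igraph` network.
#' @param node Vertex name or index.
#' @return Clustering coefficient in \[0, 1\].
#' @export
#' @examples
#' node_clustering(igraph::make_full_graph(3), 1)  # 1
node_clustering <- function(net, node) {
  net <- drop_loops(net)
  nb <- igraph::neighbors(net, node)
  k <- length(unique(nb))
  if (k < 2) return(0)
  sub <- igraph::induced_subgraph(net, unique(nb))
  igraph::ecount(sub) / (k * (k - 1) / 2)
}

# internal: local clustering for all nodes, degree<2 -> 0, loops ignored
local_clustering <- function(net) {
  net <- drop_loops(net)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  cc
}

#' Names of the implemented community metrics
#'
#' The registry of community-level topological metrics: mean degree, degree
#' assortativity, mean clustering coefficient, mean geodesic node
#' betweenness, mean closeness, mean eigenvector centrality, mean geodesic
#' distance, diameter, mean harmonic geodesic distance, cyclomatic number,
#' density, efficiency, fraction of articulation vertices, and largest
#' adjacency eigenvalue.  [community_metrics()] accepts any subset.
#'
#' @return Character vector of metric names.
#' @export
metric_registry <- function() {
  c("mean_degree", "degree_assortativity", "mean_clustering",
    "mean_betweenness", "mean_closeness", "mean_eigenvector",
    "mean_geodesic", "diameter", "mean_harmonic_geodesic",
    "cyclomatic_number", "density", "efficiency", "frac_articulation",
    "largest_eigenvalue")
}

#' Topological metrics of one community
#'
#' Metrics are computed on the induced subgraph of the community's members
#' (self-loops dropped): a community metric meant to predict functional
#' homogeneity should reflect intra-community wiring, not the community's
#' embedding.  Conventions for degenerate cases: geodesic-based means use
#' connected pairs only; diameter is the maximum over components; a
#' single-node community has clustering 0 but missing density, diameter and
#' geodesics; assortativity is missing on degree-regular subgraphs;
#' efficiency is the mean inverse geodesic over connected pairs, so it is
#' exactly the reciprocal of the harmonic mean geodesic.  A whole-network
#' clustering variant (node clustering evaluated in the full network,
#' averaged over members) is available as `context = "network"` for
#' sensitivity checks.
#'
#' @param net An `igraph` network.
#' @param members Character vector of member proteins (subset of nodes).
#' @param metrics Metric names, a subset of [metric_registry()].
#' @param context `"induced"` (default) or `"network"` (affects
#'   `mean_clustering` only).
#' @return Named numeric vector over `metrics`; `NA` where undefined.
#' @export
community_metrics <- function(net, members, metrics = metric_registry(),
                              context = c("induced", "network")) {
  context <- match.arg(context)
  unknown <- setdiff(metrics, metric_registry())
  if (length(unknown)) {
    stop("unknown metric(s): ", paste(unknown, collapse = ", "))
  }
  net <- drop_loops(net)
  stopifnot(all(members %in% igraph::V(net)$name), length(members) >= 1)
  sub <- igraph::induced_subgraph(net, members)
  nv <- igraph::vcount(sub)
  ne <- igraph::ecount(sub)

  need_dist <- any(metrics %in% c("mean_geodesic", "diameter",
                                  "mean_harmonic_geodesic", "efficiency"))
  if (need_dist && nv > 1) {
    d <- igraph::distances(sub)
    dv <- d[upper.tri(d)]
    finite <- dv[is.finite(dv)]
  } else {
    finite <- numeric(0)
  }

  val <- function(name) {
    switch(name,
      mean_degree = mean(igraph::degree(sub)),
      degree_assortativity = {
        a <- suppressWarnings(igraph::assortativity_degree(sub))
        if (is.nan(a)) NA_real_ else a
      },
      mean_clustering = if (context == "induced") {
        mean(local_clustering(sub))
      } else {
        cc <- local_clustering(net)
        mean(cc[match(members, igraph::V(net)$name)])
      },
      mean_betweenness = mean(igraph::betweenness(sub)),
      mean_closeness = if (nv > 1) {
        mean(suppressWarnings(igraph::closeness(sub)), na.rm = TRUE)
      } else NA_real_,
      mean_eigenvector = tryCatch(
        mean(igraph::eigen_centrality(sub)$vector),
        error = function(e) NA_real_),
      mean_geodesic = if (length(finite)) mean(finite) else NA_real_,
      diameter = if (length(finite)) max(finite) else NA_real_,
      mean_harmonic_geodesic =
        if (length(finite)) 1 / mean(1 / finite) else NA_real_,
      cyclomatic_number = ne - nv + igraph::components(sub)$no,
      density = if (nv > 1) ne / (nv * (nv - 1) / 2) else NA_real_,
      efficiency = if (length(finite)) mean(1 / finite) else NA_real_,
      frac_articulation =
        length(igraph::articulation_points(sub)) / nv,
      largest_eigenvalue = if (ne == 0) 0 else {
        A <- as.matrix(igraph::as_adjacency_matrix(sub))
        max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
      })
  }
  setNames(vapply(metrics, val, numeric(1)), metrics)
}

#' Metrics for every community of a sweep
#'
#' @param sweep A `"potts_sweep"`.
#' @param net The network.
#' @param metrics Metric names (subset of [metric_registry()]).
#' @param min_size Skip communities below this size (default 1 = none).
#' @return Long data.frame: `log_lambda`, `community`, `size`, `metric`,
#'   `value`.
#' @export
sweep_metrics <- function(sweep, net, metrics = metric_registry(),
                          min_size = 1) {
  net <- drop_loops(net)
  nodes <- rownames(sweep$membership)
  out <- list()
  for (g in seq_along(sweep$log_lambda)) {
    memb <- sweep$membership[, g]
    for (lab in sort(unique(memb))) {
      members <- nodes[memb == lab]
      if (length(members) < min_size) next
      v <- community_metrics(net, members, metrics)
      out[[length(out) + 1L]] <- data.frame(
        log_lambda = sweep$log_lambda[[g]], community = lab,
        size = length(members), metric = names(v), value = as.numeric(v),
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}
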