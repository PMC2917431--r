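#' Z-score similarities over interacting pairs
#'
#' The homogeneity test controls for the fact that interacting pairs are
#' more similar than random pairs: each interacting pair's similarity is
#' standardised against all interacting pairs of the network,
#' \eqn{z_{ij} = (S_{ij} - \mu)/\sigma}, where \eqn{\mu} and \eqn{\sigma}
#' are the mean and the population standard deviation (divide by `n`) of
#' `S` over all scored interacting pairs.  By construction the scored-pair
#' z-values have mean 0 and population s.d. 1, so the whole network taken
#' as one community can never look homogeneous.
#'
#' @param es An `"edge_similarity"`.
#' @return An object of class `"edge_zscores"`: `measure`, `values`
#'   (data.frame `protein_a`, `protein_b`, `z`), `mu`, `sigma`.
#' @export
zscore_edges <- function(es) {
  stopifnot(inherits(es, "edge_similarity"))
  v <- es$values$value
  if (length(v) < 2) stop("need at least 2 scored pairs to standardise")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) {
    stop("degenerate similarity: all scored pairs identical (sigma = 0)")
  }
  structure(list(measure = es$measure,
                 values = data.frame(protein_a = es$values$protein_a,
                                     protein_b = es$values$protein_b,
                                     z = (v - mu) / sigma),
                 mu = mu, sigma = sigma),
            class = "edge_zscores")
}

#' @export
print.edge_zscores <- function(x, ...) {
  cat(sprintf("Edge z-scores (%s): %d pairs, mu = %.4f, sigma = %.4f\n",
              x$measure, nrow(x$values), x$mu, x$sigma))
  invisible(x)
}

#' Per-community mean edge z-score
#'
#' For each community of a partition, averages the z-scores of edges with
#' both endpoints inside it (and both covered by the measure).  Communities
#' with no scored internal edge get `NA` — missing data, not evidence
#' against homogeneity.
#'
#' @param membership Named membership vector (or a `"potts_partition"`).
#' @param net The network the z-scores were computed on.
#' @param ez An `"edge_zscores"`.
#' @return Data.frame: `community`, `size`, `n_internal_pairs`, `mean_z`.
#' @export
community_mean_z <- function(membership, net, ez) {
  if (inherits(membership, "potts_partition")) {
    membership <- membership$membership
  }
  stopifnot(inherits(ez, "edge_zscores"))
  memb <- membership[igraph::V(net)$name]
  if (anyNA(memb)) stop("membership does not cover the network")
  ca <- memb[ez$values$protein_a]
  cb <- memb[ez$values$protein_b]
  internal <- !is.na(ca) & !is.na(cb) & ca == cb
  labs <- sort(unique(memb))
  npairs <- setNames(integer(length(labs)), labs)
  meanz <- setNames(rep(NA_real_, length(labs)), labs)
  if (any(internal)) {
    tab <- table(ca[internal])
    npairs[names(tab)] <- as.integer(tab)
    mz <- tapply(ez$values$z[internal], ca[internal], mean)
    meanz[names(mz)] <- mz
  }
  sizes <- table(memb)
  data.frame(community = labs,
             size = as.integer(sizes[as.character(labs)]),
             n_internal_pairs = as.integer(npairs),
             mean_z = as.numeric(meanz))
}

#' Aggregate z-score for a mean of individual z-scores
#'
#' \eqn{z_{agg} = \sqrt{n}\,\bar z}.  It grows with the number of pairs at
#' fixed mean, which is exactly why the homogeneity call uses the mean
#' rather than the aggregate: with a 0.3 mean, a community needs 30 or more
#' internal pairs for one-sided 0.05 significance
#' (`qnorm(0.95)/sqrt(30)` is approximately 0.300).
#'
#' @param mean_z Mean z-score.
#' @param n_pairs Number of z-scores averaged (>= 1).
#' @return The aggregate z-score.
#' @export
aggregate_z <- function(mean_z, n_pairs) {
  if (any(n_pairs < 1)) stop("aggregate z undefined for n_pairs = 0")
  sqrt(n_pairs) * mean_z
}

#' Call functionally homogeneous communities across a sweep
#'
#' One call per (resolution, community, measure): a community is
#' functionally homogeneous under a measure when its mean internal-edge
#' z-score is strictly above `threshold` (default 0.3) and it has at least
#' one scored internal pair.  Communities with no scored internal pair get
#' `homogeneous = NA` (excluded, not negative).  All community sizes are
#' returned; `meets_min_size` marks those at or above `min_size` (default
#' 4), the reporting filter used by [sweep_summary()].
#'
#' @param sweep A `"potts_sweep"`.
#' @param net The network.
#' @param ez_list Named list of `"edge_zscores"`, e.g.
#'   `list(G = ..., C = ...)`.
#' @param threshold Homogeneity threshold on the mean z (strict
#'   inequality).
#' @param min_size Reporting size filter recorded in `meets_min_size`.
#' @return Data.frame of class `"community_calls"`: `log_lambda`, `lambda`,
#'   `measure`, `community`, `size`, `n_internal_pairs`, `mean_z`,
#'   `aggregate_z`, `homogeneous`, `meets_min_size`.
#' @export
call_communities <- function(sweep, net, ez_list, threshold = 0.3,
                             min_size = 4) {
  stopifnot(inherits(sweep, "potts_sweep"))
  if (inherits(ez_list, "edge_zscores")) {
    ez_list <- setNames(list(ez_list), ez_list$measure)
  }
  out <- vector("list", length(sweep$log_lambda) * length(ez_list))
  r <- 0L
  for (g in seq_along(sweep$log_lambda)) {
    memb <- setNames(sweep$membership[, g], rownames(sweep$membership))
    for (m in names(ez_list)) {
      cz <- community_mean_z(memb, net, ez_list[[m]])
      r <- r + 1L
      out[[r]] <- data.frame(
        log_lambda = sweep$log_lambda[[g]], lambda = sweep$lambda[[g]],
        measure = m, community = cz$community, size = cz$size,
        n_internal_pairs = cz$n_internal_pairs, mean_z = cz$mean_z,
        aggregate_z = ifelse(cz$n_internal_pairs >= 1,
                             sqrt(cz$n_internal_pairs) * cz$mean_z,
                             NA_real_),
        homogeneous = ifelse(cz$n_internal_pairs >= 1,
                             cz$mean_z > threshold, NA),
        meets_min_size = cz$size >= min_size)
    }
  }
  calls <- do.call(rbind, out)
  attr(calls, "threshold") <- threshold
  attr(calls, "min_size") <- min_size
  class(calls) <- c("community_calls", "data.frame")
  calls
}

#' Per-resolution summary of homogeneity calls
#'
#' Aggregates calls to one row per (resolution, measure): the number of
#' communities at or above the reporting size, the number of proteins in
#' them, and how many of each are functionally homogeneous.
#'
#' @param calls A `"community_calls"` data.frame.
#' @return Data.frame: `log_lambda`, `measure`, `n_communities`,
#'   `n_proteins`, `n_homogeneous`, `n_proteins_homogeneous`.
#' @export
sweep_summary <- function(calls) {
  use <- calls[calls$meets_min_size, , drop = FALSE]
  if (!nrow(use)) {
    return(data.frame(log_lambda = numeric(), measure = character(),
                      n_communities = integer(), n_proteins = integer(),
                      n_homogeneous = integer(),
                      n_proteins_homogeneous = integer()))
  }
  agg <- aggregate(
    cbind(n_communities = rep(1L, nrow(use)), n_proteins = use$size,
          n_homogeneous = as.integer(use$homogeneous %in% TRUE),
          n_proteins_homogeneous = use$size *
            as.integer(use$homogeneous %in% TRUE)) ~ log_lambda + measure,
    data = use, FUN = sum)
  agg[order(agg$measure, agg$log_lambda), , drop = FALSE]
}

#' Fraction of each protein type in homogeneous communities
#'
#' For broad protein-type sets (e.g. slim-vocabulary process terms), the
#' fraction of that type's proteins that sit in a functionally homogeneous
#' community at each resolution, under one measure.
#'
#' @param calls A `"community_calls"` data.frame.
#' @param sweep The `"potts_sweep"` the calls came from.
#' @param type_sets Named list: type name -> character vector of proteins.
#' @param measure Which measure's calls to use (default `"G"`).
#' @return Data.frame: `log_lambda`, `type`, `n_type`, `fraction`.
#' @export
type_fractions <- function(calls, sweep, type_sets, measure = "G") {
  nodes <- rownames(sweep$membership)
  keep <- vapply(type_sets, function(s) length(intersect(s, nodes)) > 0,
                 TRUE)
  if (any(!keep)) {
    warning("skipping empty type sets: ",
            paste(names(type_sets)[!keep], collapse = ", "))
    type_sets <- type_sets[keep]
  }
  cc <- calls[calls$measure == measure & calls$homogeneous %in% TRUE &
                calls$meets_min_size, , drop = FALSE]
  out <- list()
  for (g in seq_along(sweep$log_lambda)) {
    ll <- sweep$log_lambda[[g]]
    hom_labels <- cc$community[cc$log_lambda == ll]
    memb <- sweep$membership[, g]
    in_hom <- nodes[memb %in% hom_labels]
    for (ty in names(type_sets)) {
      members <- intersect(type_sets[[ty]], nodes)
      out[[length(out) + 1L]] <- data.frame(
        log_lambda = ll, type = ty, n_type = length(members),
        fraction = mean(members %in% in_hom))
    }
  }
  do.call(rbind, out)
}

#' Trace one protein's community through the sweep
#'
#' A protein-centred view of the multi-resolution structure: for each grid
#' point, the size of the protein's community, the community's mean
#' clustering coefficient, and its mean internal-edge z-score under each
#' measure.  Long plateaus in these properties indicate
#' resolution-robust communities.
#'
#' @param sweep A `"potts_sweep"`.
#' @param net The network.
#' @param protein Protein identifier (must be in the network).
#' @param ez_list Named list of `"edge_zscores"` (may be empty).
#' @return Data.frame with one row per grid point: `log_lambda`,
#'   `community`, `size`, `mean_clustering`, then one `mean_z_<measure>`
#'   column per measure.
#' @export
trace_protein <- function(sweep, net, protein, ez_list = list()) {
  nodes <- rownames(sweep$membership)
  if (!protein %in% nodes) stop("unknown protein: ", protein)
  net <- drop_loops(net)
  out <- vector("list", length(sweep$log_lambda))
  for (g in seq_along(sweep$log_lambda)) {
    memb <- setNames(sweep$membership[, g], nodes)
    lab <- memb[[protein]]
    members <- nodes[memb == lab]
    sub <- igraph::induced_subgraph(net, members)
    row <- data.frame(log_lambda = sweep$log_lambda[[g]], community = lab,
                      size = length(members),
                      mean_clustering = mean(local_clustering(sub)))
    for (m in names(ez_list)) {
      cz <- community_mean_z(memb, net, ez_list[[m]])
      row[[paste0("mean_z_", m)]] <-
        cz$mean_z[match(lab, cz$community)]
    }
    out[[g]] <- row
  }
  do.call(rbind, out)
}
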