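#' Potts energy of a partition
#'
#' The quality function minimised by the community detection is
#' \deqn{H = -\sum_{i \ne j} \left(B_{ij} - \lambda \frac{k_i k_j}{2W}\right)
#'   \delta(s_i, s_j),}
#' summed over ordered pairs of distinct nodes, where \eqn{B} is the
#' adjacency matrix, \eqn{k_i} the degree, \eqn{W} the number of edges and
#' \eqn{\lambda} the resolution parameter.  At \eqn{\lambda = 1} this is
#' \eqn{-2W} times Newman-Girvan modularity (up to the self-pair convention);
#' larger \eqn{\lambda} penalises grouping and favours smaller communities.
#' Self-loops are dropped before evaluation: a self-pair's contribution is
#' identical in every partition, so it cannot affect any optimum.
#'
#' @param net An `igraph` network.
#' @param membership Community assignment: integer vector, either named by
#'   vertex or in vertex order, covering every node.
#' @param lambda Resolution parameter (\eqn{\ge 0}; 0 permitted so the
#'   single-community limit can be evaluated exactly).
#' @return The energy `H` (a scalar).
#' @export
#' @examples
#' g <- igraph::make_full_graph(3)
#' potts_energy(g, c(1, 1, 1), lambda = 1)  # -2
potts_energy <- function(net, membership, lambda) {
  stopifnot(lambda >= 0)
  net <- drop_loops(net)
  memb <- align_membership(net, membership)
  k <- igraph::degree(net)
  two_w <- 2 * igraph::ecount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  internal <- memb[el[, 1]] == memb[el[, 2]]
  sum_b <- 2 * sum(internal)                       # ordered pairs
  kc <- tapply(k, memb, sum)                       # degree sum per community
  kc2 <- tapply(k^2, memb, sum)
  sum_null <- sum(kc^2 - kc2) / two_w              # excludes i == j
  -(sum_b - lambda * sum_null)
}

# internal: coerce a (possibly named) membership to vertex order, validate
align_membership <- function(net, membership) {
  vn <- igraph::V(net)$name
  if (!is.null(names(membership))) {
    if (is.null(vn)) stop("named membership but unnamed vertices")
    if (!all(vn %in% names(membership))) {
      stop("membership does not cover all nodes")
    }
    membership <- membership[vn]
  } else if (length(membership) != igraph::vcount(net)) {
    stop("membership does not cover all nodes")
  }
  if (anyNA(membership)) stop("membership contains missing assignments")
  as.integer(as.factor(membership))
}

#' Greedy Potts-energy minimisation at one resolution
#'
#' A seeded Louvain-style two-phase greedy heuristic: repeated single-node
#' moves to the neighbouring (or a fresh singleton) community that most
#' decreases the energy, followed by aggregation of communities into
#' super-nodes, iterated until no move improves.  Ties among equally good
#' moves are broken towards the lowest community label; the node visit order
#' is shuffled deterministically from `seed`.  Like all greedy modularity
#' optimisers it returns a local optimum; near-optimal partitions are
#' typically highly degenerate, so downstream analyses should compare
#' energies and recovered structure rather than exact label sets.
#'
#' @param net Connected `igraph` network (self-loops are dropped internally).
#' @param lambda Resolution parameter, > 0.
#' @param seed Integer seed for the visit-order shuffle.
#' @param init Optional warm-start membership (named by vertex or in vertex
#'   order); defaults to all-singletons.
#' @return A list of class `"potts_partition"`: `membership` (named integer
#'   vector, labels compacted to `1..n_comm`), `lambda`, `energy`,
#'   `n_communities`.
#' @export
potts_optimize <- function(net, lambda, seed = 1L, init = NULL) {
  stopifnot(lambda > 0)
  net0 <- drop_loops(net)
  n <- igraph::vcount(net0)
  el <- igraph::as_edgelist(net0, names = FALSE)
  edges <- cbind(el[, 1], el[, 2])
  w <- rep(1, nrow(edges))
  k <- as.numeric(igraph::degree(net0))
  two_w <- sum(k)
  if (two_w == 0) stop("network has no edges")

  if (is.null(init)) {
    assign0 <- seq_len(n)
  } else {
    assign0 <- align_membership(net0, init)
  }

  # node_map[i] = current super-node of original node i
  node_map <- seq_len(n)
  cur_edges <- edges
  cur_w <- w
  cur_k <- k
  cur_n <- n
  cur_init <- assign0
  level_seed <- as.integer(seed %% .Machine$integer.max)

  repeat {
    memb <- louvain_one_level(cur_n, as.integer(cur_edges[, 1] - 1L),
                              as.integer(cur_edges[, 2] - 1L),
                              as.numeric(cur_w), cur_k, two_w, lambda,
                              as.integer(cur_init - 1L), level_seed) + 1L
    memb <- as.integer(as.factor(memb))
    n_comm <- max(memb)
    changed <- !all(memb == cur_init)
    # with a singleton init "no change" means no super-node merge improves
    # either, i.e. a two-phase local optimum; with a warm start we still
    # aggregate once so whole-community merges get considered
    if (!changed && all(cur_init == seq_len(cur_n))) break
    node_map <- memb[node_map]
    if (n_comm == 1L) break
    # aggregate: communities become super-nodes, parallel edges summed,
    # internal edges become self-loops
    a <- memb[cur_edges[, 1]]
    b <- memb[cur_edges[, 2]]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- (lo - 1) * n_comm + hi
    agg <- rowsum(cur_w, key)
    ukey <- as.numeric(rownames(agg))
    cur_edges <- cbind(((ukey - 1) %/% n_comm) + 1, ((ukey - 1) %% n_comm) + 1)
    cur_w <- as.numeric(agg[, 1])
    cur_k <- as.numeric(rowsum(cur_k, memb)[, 1])
    cur_n <- n_comm
    cur_init <- seq_len(cur_n)
    level_seed <- as.integer((level_seed * 69069 + 1) %% 2147483647)
  }

  membership <- as.integer(as.factor(node_map))
  names(membership) <- igraph::V(net0)$name
  structure(list(membership = membership, lambda = lambda,
                 energy = potts_energy(net0, membership, lambda),
                 n_communities = max(membership)),
            class = "potts_partition")
}

#' @export
print.potts_partition <- function(x, ...) {
  cat(sprintf("Potts partition: lambda = %g, %d communities, H = %.4f\n",
              x$lambda, x$n_communities, x$energy))
  invisible(x)
}

#' Sweep the resolution parameter over a logarithmic grid
#'
#' Runs [potts_optimize()] at each grid point of
#' `log10(lambda) = log_min, log_min + step, ..., log_max` (defaults
#' \eqn{-1 \le \log \lambda \le 3}) and relabels communities across adjacent
#' resolutions so that the same label follows the same group of nodes as the
#' resolution changes (see [relabel_sweep()]).  By default each grid point
#' warm-starts from the previous partition, which roughly halves runtime;
#' set `warm_start = FALSE` for fully independent runs.
#'
#' @param net Connected `igraph` network.
#' @param log_min,log_max Sweep range on the log10 scale; `log_min < log_max`.
#' @param step Grid spacing on the log10 scale (> 0); 0.01 matches the
#'   published protocol, coarser grids are appropriate for testing.
#' @param seed Integer seed; per-grid-point optimiser seeds are derived
#'   deterministically from it.
#' @param warm_start Warm-start each grid point from the previous partition.
#' @param relabel Apply the cross-resolution labelling convention.
#' @return An object of class `"potts_sweep"`: `log_lambda` (grid),
#'   `lambda`, `membership` (nodes x grid integer matrix, rownames =
#'   vertices), `energy`, `n_communities`, plus the call parameters.
#' @export
potts_sweep <- function(net, log_min = -1, log_max = 3, step = 0.01,
                        seed = 1L, warm_start = TRUE, relabel = TRUE) {
  stopifnot(log_min < log_max, step > 0)
  grid <- seq(log_min, log_max, by = step)
  net0 <- drop_loops(net)
  n <- igraph::vcount(net0)
  memb <- matrix(NA_integer_, n, length(grid),
                 dimnames = list(igraph::V(net0)$name, NULL))
  energy <- numeric(length(grid))
  ncomm <- integer(length(grid))
  prev <- NULL
  for (g in seq_along(grid)) {
    lam <- 10^grid[[g]]
    sub_seed <- (as.integer(seed) + 7919L * g) %% .Machine$integer.max
    fit <- potts_optimize(net0, lam, seed = sub_seed,
                          init = if (warm_start) prev else NULL)
    memb[, g] <- fit$membership
    energy[[g]] <- fit$energy
    ncomm[[g]] <- fit$n_communities
    prev <- fit$membership
  }
  sw <- structure(list(log_lambda = grid, lambda = 10^grid,
                       membership = memb, energy = energy,
                       n_communities = ncomm, seed = seed,
                       warm_start = warm_start, relabeled = FALSE),
                  class = "potts_sweep")
  if (relabel) sw <- relabel_sweep(sw) else sw
}

#' Cross-resolution community labelling
#'
#' Gives communities identities that persist across the resolution sweep.
#' For each pair of adjacent partitions the node-overlap score between
#' community \eqn{K_i} of the higher-resolution partition and \eqn{L_j} of
#' the lower-resolution one is the Jaccard index
#' \eqn{W_{ij} = |K_i \cap L_j| / |K_i \cup L_j|}.  Starting with the
#' largest \eqn{W_{ij}}, community \eqn{i} is relabelled as community
#' \eqn{j}; matching proceeds in decreasing \eqn{W_{ij}} with each community
#' matched at most once (ties broken by larger intersection, then lower old
#' label), and when the higher-resolution partition has more communities
#' than the lower (s > t) the unmatched ones receive fresh labels.  Applied
#' sequentially from the lowest-resolution end of the grid, so a label
#' introduced at a split persists to higher resolutions.  A link-overlap
#' variant is available via `overlap = "intersection"` (raw
#' \eqn{|K_i \cap L_j|}); the labelling is typically near-identical.
#'
#' Relabelling only renames communities: which nodes are co-clustered at
#' each resolution is untouched.
#'
#' @param sweep A `"potts_sweep"` object (>= 2 grid points).
#' @param overlap `"jaccard"` (default) or `"intersection"`.
#' @return The sweep with consistent labels (`relabeled = TRUE`).
#' @export
relabel_sweep <- function(sweep, overlap = c("jaccard", "intersection")) {
  overlap <- match.arg(overlap)
  memb <- sweep$membership
  if (ncol(memb) < 2L) stop("need at least 2 partitions to relabel")
  out <- memb
  out[, 1] <- as.integer(as.factor(memb[, 1]))
  next_label <- max(out[, 1])
  for (g in 2:ncol(memb)) {
    fine <- as.integer(as.factor(memb[, g]))   # higher resolution (larger lambda)
    coarse <- out[, g - 1]                     # already labelled
    map <- match_communities(fine, coarse, overlap)
    fresh <- which(is.na(map))
    if (length(fresh)) {
      map[fresh] <- next_label + seq_along(fresh)
      next_label <- next_label + length(fresh)
    }
    out[, g] <- map[fine]
    next_label <- max(next_label, max(out[, g]))
  }
  sweep$membership <- out
  sweep$relabeled <- TRUE
  sweep
}

# internal: one-to-one greedy matching of fine communities to coarse labels.
# Returns map[fine_label] = coarse label or NA (unmatched).
match_communities <- function(fine, coarse, overlap = "jaccard") {
  tab <- table(fine, coarse)
  fl <- as.integer(rownames(tab))
  cl <- as.integer(colnames(tab))
  sizes_f <- rowSums(tab)
  sizes_c <- colSums(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  inter <- tab[idx]
  score <- if (overlap == "jaccard") {
    inter / (sizes_f[idx[, 1]] + sizes_c[idx[, 2]] - inter)
  } else {
    inter
  }
  ord <- order(-score, -inter, fl[idx[, 1]], cl[idx[, 2]])
  map <- rep(NA_integer_, max(fl))
  used <- logical(max(cl))
  for (r in ord) {
    f <- fl[idx[r, 1]]
    c_ <- cl[idx[r, 2]]
    if (is.na(map[f]) && !used[c_]) {
      map[f] <- c_
      used[c_] <- TRUE
    }
  }
  map
}

#' @export
print.potts_sweep <- function(x, ...) {
  cat(sprintf(
    "Potts resolution sweep: %d grid points, log10(lambda) in [%g, %g]\n",
    length(x$log_lambda), min(x$log_lambda), max(x$log_lambda)))
  cat(sprintf("  %d nodes; communities: %d (coarsest) to %d (finest)\n",
              nrow(x$membership), min(x$n_communities),
              max(x$n_communities)))
  cat(sprintf("  warm_start = %s, relabeled = %s, seed = %s\n",
              x$warm_start, x$relabeled, format(x$seed)))
  invisible(x)
}

#' @export
summary.potts_sweep <- function(object, ...) {
  df <- data.frame(log_lambda = object$log_lambda, lambda = object$lambda,
                   n_communities = object$n_communities,
                   mean_size = nrow(object$membership) / object$n_communities,
                   energy = object$energy)
  class(df) <- c("summary.potts_sweep", "data.frame")
  df
}

#' @export
print.summary.potts_sweep <- function(x, ...) {
  cat("Resolution sweep summary (one row per grid point):\n")
  print.data.frame(head(as.data.frame(x), 12), row.names = FALSE)
  if (nrow(x) > 12) cat(sprintf("  ... %d more rows\n", nrow(x) - 12))
  invisible(x)
}

#' @export
plot.potts_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$log_lambda, x$n_communities, type = "l",
                 xlab = expression(log[10](lambda)),
                 ylab = "number of communities", ...)
  graphics::plot(x$log_lambda, nrow(x$membership) / x$n_communities,
                 type = "l", log = "y",
                 xlab = expression(log[10](lambda)),
                 ylab = "mean community size", ...)
  invisible(x)
}

#' Long-format view of a sweep
#'
#' @param x A `"potts_sweep"`.
#' @param ... Unused.
#' @return Data.frame with columns `protein`, `log_lambda`,
#'   `community_label`.
#' @export
as.data.frame.potts_sweep <- function(x, ...) {
  data.frame(
    protein = rep(rownames(x$membership), times = ncol(x$membership)),
    log_lambda = rep(x$log_lambda, each = nrow(x$membership)),
    community_label = as.vector(x$membership))
}

#' Membership vector at one grid point
#'
#' @param sweep A `"potts_sweep"`.
#' @param log_lambda Grid value (matched to the nearest grid point).
#' @return Named integer membership vector.
#' @export
sweep_partition <- function(sweep, log_lambda) {
  g <- which.min(abs(sweep$log_lambda - log_lambda))
  setNames(sweep$membership[, g], rownames(sweep$membership))
}

#' Normalized mutual information between two partitions
#'
#' \eqn{2 I(A;B) / (H(A) + H(B))} over the nodes common to both label
#' vectors; 1 for identical partitions, 0 for independent ones.  Two
#' identical trivial partitions (zero entropy on both sides) score 1.
#'
#' @param a,b Named membership vectors over the same node set.
#' @return NMI in \[0, 1\].
#' @export
partition_nmi <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (!length(common)) stop("no common nodes between partitions")
  tab <- table(a[common], b[common])
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  ha <- -sum(pj * log(pj))
  hb <- -sum(pk * log(pk))
  p <- tab / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pj, pk)[nz]))
  if (ha + hb == 0) return(1)  # both trivial, necessarily identical
  2 * mi / (ha + hb)
}

#' Resolution above which every node is its own community
#'
#' All entries of the interaction matrix `J` are negative once
#' \eqn{\lambda > \max_{(i,j) \in E} 2W/(k_i k_j)}; beyond that bound the
#' all-singletons partition is the unique optimum.
#'
#' @param net An `igraph` network.
#' @return The bound (a scalar).
#' @export
singleton_lambda_bound <- function(net) {
  net <- drop_loops(net)
  k <- igraph::degree(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  max(2 * igraph::ecount(net) / (k[el[, 1]] * k[el[, 2]]))
}
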