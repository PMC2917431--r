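# Shared fixtures and independent oracles, all built in code.

# two triangles joined by one bridge edge (6 nodes)
bridged_triangles <- function() {
  el <- rbind(c("a", "b"), c("b", "c"), c("a", "c"),
              c("d", "e"), c("e", "f"), c("d", "f"), c("c", "d"))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# two 4-cliques joined by one bridge edge (8 nodes)
bridged_cliques <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  g <- igraph::add_edges(g, c(4, 5))
  igraph::V(g)$name <- letters[1:8]
  g
}

# toy shared-annotation fixture: 5 proteins over a small DAG
toy_annotations <- function() {
  dag <- list(root = character(), t1 = "root", t2 = "t1", t3 = "root")
  propagate_annotations(annotation_set(
    list(p1 = c("t1", "t2"), p2 = c("t1", "t2"), p3 = "t1", p4 = "t3",
         p5 = character()),
    dag, root = "root"))
}

# enumerate all set partitions of 1..n as a list of membership vectors
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    k <- max(p)
    for (lab in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, lab)
  }
  out
}

# exhaustive-minimum Potts energy (independent of the optimiser path):
# brute-force H over every partition, using a direct pair-sum evaluation
exhaustive_min_energy <- function(net, lambda) {
  net0 <- igraph::delete_edges(net, which(igraph::which_loop(net)))
  n <- igraph::vcount(net0)
  A <- as.matrix(igraph::as_adjacency_matrix(net0))
  k <- rowSums(A)
  two_w <- sum(k)
  J <- A - lambda * outer(k, k) / two_w
  diag(J) <- 0
  best <- Inf
  for (p in all_partitions(n)) {
    same <- outer(p, p, "==")
    diag(same) <- FALSE
    h <- -sum(J[same])
    if (h < best) best <- h
  }
  best
}

# brute-force shared-set count: scan all proteins with a superset test
brute_shared_count <- function(sets, i, j) {
  common <- intersect(sets[[i]], sets[[j]])
  if (!length(common)) return(length(sets))
  sum(vapply(sets, function(s) all(common %in% s), TRUE))
}

# brute-force per-node clustering: triangles / triples by neighbour pairs
brute_clustering <- function(net, v) {
  nb <- as.integer(igraph::neighbors(net, v))
  nb <- setdiff(unique(nb), as.integer(igraph::V(net)[v]))
  k <- length(nb)
  if (k < 2) return(0)
  tri <- 0
  for (x in seq_len(k - 1)) {
    for (y in (x + 1):k) {
      if (igraph::are_adjacent(net, nb[x], nb[y])) tri <- tri + 1
    }
  }
  tri / (k * (k - 1) / 2)
}

# single-lambda sweep wrapper so call-level functions can be unit tested
one_point_sweep <- function(fit, log_lambda, seed = 1L) {
  structure(list(
    log_lambda = log_lambda, lambda = 10^log_lambda,
    membership = matrix(fit$membership, ncol = 1,
                        dimnames = list(names(fit$membership), NULL)),
    energy = fit$energy, n_communities = fit$n_communities,
    seed = seed, warm_start = FALSE, relabeled = TRUE),
    class = "potts_sweep")
}

# planted fixture with annotations/growth, small enough for fast loops
small_benchmark <- function(seed, fidelity = 0.9, effect_size = 2,
                            noise_sd = 0.5) {
  gen <- generate_planted_network(3, 3, 12, seed = seed)
  ann <- generate_annotations(gen$structure, fidelity = fidelity,
                              seed = seed + 1000L)
  gm <- generate_growth_profiles(gen$structure, n_conditions = 100,
                                 effect_size = effect_size,
                                 noise_sd = noise_sd, seed = seed + 2000L)
  list(network = gen$network, structure = gen$structure, annotations = ann,
       growth = gm)
}
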