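test_that("energy evaluates the ordered-pair Potts sum", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  expect_equal(potts_energy(k3, c(a = 1, b = 1, c = 1), 1), -2)
  expect_equal(potts_energy(k3, c(a = 1, b = 2, c = 3), 1), 0)
  # merge exactly neutral at lambda = 1.5 (J_ij = 1 - lambda * 2/3)
  expect_equal(potts_energy(k3, c(a = 1, b = 1, c = 1), 1.5), 0)
  expect_gt(potts_energy(k3, c(a = 1, b = 1, c = 1), 2), 0)
  expect_error(potts_energy(k3, c(a = 1, b = 1), 1), "cover")
})

test_that("greedy optimiser attains the exhaustive minimum on fixtures", {
  for (g in list(bridged_triangles(), bridged_cliques())) {
    for (lam in c(0.5, 1, 2)) {
      fit <- potts_optimize(g, lam, seed = 42)
      hmin <- exhaustive_min_energy(g, lam)
      expect_gte(fit$energy, hmin - 1e-9)
      if (lam == 1) expect_equal(fit$energy, hmin)
    }
  }
  # the lambda = 1 optimum splits the bridged triangles into the triangles
  fit <- potts_optimize(bridged_triangles(), 1, seed = 7)
  m <- fit$membership
  expect_equal(fit$n_communities, 2)
  expect_equal(length(unique(m[c("a", "b", "c")])), 1)
  expect_equal(length(unique(m[c("d", "e", "f")])), 1)
})

test_that("optimiser at least matches single-community and singleton baselines", {
  gen <- generate_planted_network(2, 2, 8, seed = 13)
  g <- gen$network
  n <- igraph::vcount(g)
  for (lam in c(0.3, 1, 5)) {
    fit <- potts_optimize(g, lam, seed = 3)
    all_one <- setNames(rep(1, n), igraph::V(g)$name)
    singles <- setNames(seq_len(n), igraph::V(g)$name)
    expect_lte(fit$energy, potts_energy(g, all_one, lam) + 1e-9)
    expect_lte(fit$energy, potts_energy(g, singles, lam) + 1e-9)
  }
})

test_that("resolution limits: one community at lambda -> 0, singletons beyond the J bound", {
  fixtures <- list(bridged_triangles(), bridged_cliques(),
                   generate_planted_network(2, 2, 8, seed = 2)$network)
  for (g in fixtures) {
    expect_equal(potts_optimize(g, 1e-6, seed = 1)$n_communities, 1)
    lam <- singleton_lambda_bound(g) * 1.001
    expect_equal(potts_optimize(g, lam, seed = 1)$n_communities,
                 igraph::vcount(g))
  }
})

test_that("sweep recovers planted structure at two scales", {
  gen <- generate_planted_network(seed = 5)
  sw <- potts_sweep(gen$network, -1, 3, 0.1, seed = 5)
  expect_equal(length(sw$log_lambda), 41)
  nmi_c <- vapply(seq_along(sw$log_lambda), function(g)
    partition_nmi(sweep_partition(sw, sw$log_lambda[g]),
                  gen$structure$coarse_labels), 1)
  nmi_f <- vapply(seq_along(sw$log_lambda), function(g)
    partition_nmi(sweep_partition(sw, sw$log_lambda[g]),
                  gen$structure$fine_labels), 1)
  expect_gte(max(nmi_c), 0.9)
  expect_gte(max(nmi_f), 0.9)
  # fine structure resolved at a strictly larger resolution than coarse
  expect_gt(sw$log_lambda[which.max(nmi_f)], sw$log_lambda[which.max(nmi_c)])
  # mean community size decreases with resolution (up to optimiser noise)
  rho <- cor(sw$log_lambda, nrow(sw$membership) / sw$n_communities,
             method = "spearman")
  expect_lt(rho, 0)
})

test_that("grid arithmetic and determinism of the sweep", {
  g <- bridged_cliques()
  sw <- potts_sweep(g, -1, 3, 0.5, seed = 1)
  expect_equal(length(sw$log_lambda), 9)
  sw2 <- potts_sweep(g, -1, 3, 0.5, seed = 1)
  expect_identical(sw$membership, sw2$membership)
  # independent runs are a valid alternative mode: every grid point's
  # energy still beats (or matches) both trivial baselines
  sw3 <- potts_sweep(g, -1, 3, 0.5, seed = 1, warm_start = FALSE)
  n <- igraph::vcount(g)
  for (i in seq_along(sw3$log_lambda)) {
    lam <- sw3$lambda[i]
    base <- min(potts_energy(g, setNames(rep(1, n), igraph::V(g)$name), lam),
                0)  # all-singletons energy is 0
    expect_lte(sw3$energy[i], base + 1e-9)
    expect_lte(sw$energy[i], base + 1e-9)
  }
})

test_that("cross-resolution relabeling matches overlaps and preserves co-clustering", {
  # identical adjacent partitions keep identical labels
  m <- cbind(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))
  sw <- structure(list(log_lambda = c(0, 1), lambda = c(1, 10),
                       membership = `rownames<-`(m, letters[1:4]),
                       energy = c(0, 0), n_communities = c(2L, 2L),
                       seed = 1L, warm_start = FALSE, relabeled = FALSE),
                  class = "potts_sweep")
  out <- relabel_sweep(sw)
  expect_identical(out$membership[, 2], out$membership[, 1])

  # worked overlap example: {1,2,3},{4,5} vs {1,2},{3,4,5}
  # (columns ordered coarse -> fine; Jaccard 2/3 tie resolved by lower
  # old label, so {1,2} -> label of {1,2,3} and {3,4,5} -> label of {4,5})
  m2 <- cbind(c(1L, 1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L, 2L))
  sw2 <- structure(list(log_lambda = c(0, 1), lambda = c(1, 10),
                        membership = `rownames<-`(m2, paste0("n", 1:5)),
                        energy = c(0, 0), n_communities = c(2L, 2L),
                        seed = 1L, warm_start = FALSE, relabeled = FALSE),
                   class = "potts_sweep")
  out2 <- relabel_sweep(sw2)
  expect_equal(unname(out2$membership[c("n1", "n2"), 2]), c(1L, 1L))
  expect_equal(unname(out2$membership[c("n4", "n5"), 2]), c(2L, 2L))

  # a 2 -> 3 community split introduces exactly one fresh label
  m3 <- cbind(c(1L, 1L, 1L, 2L, 2L, 2L), c(1L, 1L, 2L, 2L, 3L, 3L))
  sw3 <- structure(list(log_lambda = c(0, 1), lambda = c(1, 10),
                        membership = `rownames<-`(m3, paste0("n", 1:6)),
                        energy = c(0, 0), n_communities = c(2L, 3L),
                        seed = 1L, warm_start = FALSE, relabeled = FALSE),
                   class = "potts_sweep")
  out3 <- relabel_sweep(sw3)
  labs2 <- unique(out3$membership[, 2])
  expect_equal(length(setdiff(labs2, out3$membership[, 1])), 1)

  # relabeling never changes which nodes are co-clustered
  gen <- generate_planted_network(2, 2, 8, seed = 8)
  raw <- potts_sweep(gen$network, -1, 3, 0.5, seed = 8, relabel = FALSE)
  rel <- relabel_sweep(raw)
  for (g in seq_along(raw$log_lambda)) {
    expect_equal(partition_nmi(
      setNames(raw$membership[, g], rownames(raw$membership)),
      setNames(rel$membership[, g], rownames(rel$membership))), 1)
  }
})

test_that("optimiser agrees with an independent community detector at lambda 1", {
  # igraph's Louvain maximises the same objective at resolution 1; on an
  # easy planted fixture both should find a partition of equal energy
  gen <- generate_planted_network(2, 2, 10, seed = 31)
  g <- gen$network
  fit <- potts_optimize(g, 1, seed = 31)
  ig <- igraph::cluster_louvain(g, resolution = 1)
  h_ig <- potts_energy(g, setNames(igraph::membership(ig),
                                   igraph::V(g)$name), 1)
  expect_lte(fit$energy, h_ig + 1e-9)
})
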