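make_ez <- function(pa, pb, values, measure = "G") {
  es <- structure(list(measure = measure,
                       values = data.frame(protein_a = pa, protein_b = pb,
                                           value = values),
                       coverage = unique(c(pa, pb)),
                       mean_interacting = mean(values),
                       mean_all_pairs = NA_real_),
                  class = "edge_similarity")
  zscore_edges(es)
}

test_that("edge z-scores are population-standardised over interacting pairs", {
  v <- c(0.1, 0.2, 0.3, 0.4)
  ez <- make_ez(c("a", "b", "c", "d"), c("b", "c", "d", "a"), v)
  sig <- sqrt(mean((v - mean(v))^2))
  expect_equal(ez$values$z[4], (0.4 - 0.25) / sig)
  expect_equal(mean(ez$values$z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(ez$values$z^2)), 1, tolerance = 1e-9)
  expect_error(make_ez(c("a", "b"), c("b", "c"), c(0.5, 0.5)),
               "degenerate")
})

test_that("community mean z agrees with a brute-force edge scan", {
  gen <- generate_planted_network(2, 2, 8, seed = 23)
  net <- gen$network
  a <- propagate_annotations(generate_annotations(gen$structure,
                                                  fidelity = 0.8,
                                                  seed = 23))
  ez <- zscore_edges(edge_similarity(net, "G", a, all_pairs_sample = 0))

  # the whole network as one community recovers the zero mean
  whole <- setNames(rep(1L, igraph::vcount(net)), igraph::V(net)$name)
  cz <- community_mean_z(whole, net, ez)
  expect_equal(cz$mean_z, 0, tolerance = 1e-9)
  expect_equal(cz$n_internal_pairs, nrow(ez$values))

  # random bipartition vs direct scan over the z table
  memb <- withr::with_seed(9, setNames(sample(1:2, igraph::vcount(net),
                                              replace = TRUE),
                                       igraph::V(net)$name))
  cz2 <- community_mean_z(memb, net, ez)
  for (lab in 1:2) {
    inside <- memb[ez$values$protein_a] == lab &
      memb[ez$values$protein_b] == lab
    expect_equal(cz2$n_internal_pairs[cz2$community == lab], sum(inside))
    expect_equal(cz2$mean_z[cz2$community == lab],
                 mean(ez$values$z[inside]))
  }

  # a community holding exactly one scored edge inherits that edge's z
  ez1 <- make_ez(c("x", "y", "z"), c("y", "z", "x"), c(0.1, 0.5, 0.9))
  g3 <- build_network(data.frame(protein_a = c("x", "y", "z"),
                                 protein_b = c("y", "z", "x"),
                                 itype = "A"), "A")
  memb3 <- c(x = 1L, y = 1L, z = 2L)
  cz3 <- community_mean_z(memb3, g3, ez1)
  expect_equal(cz3$mean_z[cz3$community == 1],
               ez1$values$z[ez1$values$protein_a == "x" &
                              ez1$values$protein_b == "y"])
})

test_that("aggregate z justifies the 0.3 threshold at 30 pairs", {
  expect_equal(aggregate_z(0.3, 30), 0.3 * sqrt(30))
  # one-sided 0.05 critical mean for n pairs is qnorm(0.95)/sqrt(n),
  # which rounds to 0.3 at n = 30 and drops below 0.3 from n = 31 on
  expect_equal(round(qnorm(0.95) / sqrt(30), 1), 0.3)
  expect_lt(qnorm(0.95) / sqrt(31), 0.3)
  expect_equal(aggregate_z(0.7, 1), 0.7)
  expect_equal(aggregate_z(0.5, 4), 1)
  expect_error(aggregate_z(0.5, 0), "undefined")
})

test_that("homogeneity calls use a strict threshold and report sizes", {
  ez <- make_ez(c("a", "b", "c", "d"), c("b", "c", "d", "a"),
                c(0.1, 0.2, 0.3, 0.4))
  g <- build_network(data.frame(protein_a = c("a", "b", "c", "d"),
                                protein_b = c("b", "c", "d", "a"),
                                itype = "A"), "A")
  fit <- potts_optimize(g, 1, seed = 1)
  sw <- one_point_sweep(fit, 0)
  calls <- call_communities(sw, g, list(G = ez), threshold = 0.3)
  expect_s3_class(calls, "community_calls")
  # a mean z exactly at the threshold is not homogeneous (strict rule):
  # re-call with the threshold set to a community's own mean z
  cc <- calls[calls$measure == "G" & !is.na(calls$mean_z), ][1, ]
  calls2 <- call_communities(sw, g, list(G = ez), threshold = cc$mean_z)
  at_bound <- calls2[calls2$community == cc$community, ]
  expect_false(at_bound$homogeneous[[1]])

  # zero scored internal edges -> NA call, not a negative
  ez_ab <- make_ez(c("a", "a", "b"), c("b", "c", "c"), c(0.2, 0.5, 0.8))
  g2 <- build_network(data.frame(protein_a = c("a", "a", "b", "d"),
                                 protein_b = c("b", "c", "c", "a"),
                                 itype = "A"), "A")
  memb <- c(a = 1L, b = 1L, c = 1L, d = 2L)
  swd <- one_point_sweep(structure(list(membership = memb, lambda = 1,
                                        energy = 0, n_communities = 2L),
                                   class = "potts_partition"), 0)
  calls3 <- call_communities(swd, g2, list(G = ez_ab))
  expect_true(is.na(calls3$homogeneous[calls3$community == 2]))
})

test_that("sweep summaries count communities and proteins by measure", {
  # three communities of sizes 5, 3, 2; only the 5-community homogeneous
  memb <- setNames(c(rep(1L, 5), rep(2L, 3), rep(3L, 2)),
                   paste0("p", 1:10))
  pairs <- t(combn(paste0("p", 1:5), 2))
  others <- rbind(c("p6", "p7"), c("p7", "p8"), c("p9", "p10"),
                  c("p5", "p6"), c("p8", "p9"))
  pa <- c(pairs[, 1], others[, 1])
  pb <- c(pairs[, 2], others[, 2])
  vals <- c(rep(0.9, nrow(pairs)), rep(0.1, nrow(others)))
  ez <- make_ez(pa, pb, vals)
  g <- build_network(data.frame(protein_a = pa, protein_b = pb,
                                itype = "A"), "A")
  sw <- one_point_sweep(structure(list(membership = memb, lambda = 1,
                                       energy = 0, n_communities = 3L),
                                  class = "potts_partition"), 0.5)
  calls <- call_communities(sw, g, list(G = ez))
  s <- sweep_summary(calls)
  expect_equal(s$n_communities, 1)           # only size >= 4 reported
  expect_equal(s$n_proteins, 5)
  expect_equal(s$n_homogeneous, 1)
  expect_equal(s$n_proteins_homogeneous, 5)

  # no homogeneous communities -> zero columns
  calls0 <- call_communities(sw, g, list(G = ez), threshold = 99)
  s0 <- sweep_summary(calls0)
  expect_equal(s0$n_homogeneous, 0)
  expect_equal(s0$n_proteins_homogeneous, 0)
})

test_that("permutation null centres community mean z at zero", {
  grand <- vapply(1:20, function(s) {
    b <- small_benchmark(s)
    a <- b$annotations
    a$annotations <- withr::with_seed(s + 99,
      setNames(a$annotations[sample(length(a$annotations))],
               names(a$annotations)))
    a <- propagate_annotations(a)
    ez <- zscore_edges(edge_similarity(b$network, "G", a,
                                       all_pairs_sample = 0))
    fit <- potts_optimize(b$network, 10^0.6, seed = s)
    cz <- community_mean_z(fit$membership, b$network, ez)
    mean(cz$mean_z, na.rm = TRUE)
  }, 1)
  expect_lt(abs(mean(grand)), 3 * sd(grand) / sqrt(length(grand)))
})

test_that("type fractions span their trivial extremes", {
  b <- small_benchmark(3, fidelity = 1)
  a <- propagate_annotations(b$annotations)
  ez <- list(G = zscore_edges(edge_similarity(b$network, "G", a,
                                              all_pairs_sample = 0)))
  fit <- potts_optimize(b$network, 10^0.6, seed = 3)
  sw <- one_point_sweep(fit, 0.6)
  calls <- call_communities(sw, b$network, ez)
  hom <- calls$community[calls$homogeneous %in% TRUE & calls$meets_min_size]
  expect_gt(length(hom), 0)
  inside <- names(fit$membership)[fit$membership %in% hom]
  outside <- setdiff(names(fit$membership), inside)
  types <- list(all_in = inside[1:4], all_out = outside)
  tf <- type_fractions(calls, sw, types)
  expect_equal(tf$fraction[tf$type == "all_in"], 1)
  if (length(outside)) {
    expect_equal(tf$fraction[tf$type == "all_out"], 0)
  }
  expect_warning(type_fractions(calls, sw, list(empty = character(0),
                                                ok = inside[1:2])),
                 "empty")
})

test_that("protein traces follow community membership across the sweep", {
  b <- small_benchmark(4, fidelity = 1)
  a <- propagate_annotations(b$annotations)
  ez <- list(G = zscore_edges(edge_similarity(b$network, "G", a,
                                              all_pairs_sample = 0)))
  sw <- potts_sweep(b$network, -1, 3, 0.5, seed = 4)
  p <- names(b$structure$fine_labels)[1]
  tr <- trace_protein(sw, b$network, p, ez)
  expect_equal(nrow(tr), length(sw$log_lambda))
  # beyond the singleton bound the community has size 1 and no scored edge
  expect_equal(tr$size[nrow(tr)], 1)
  expect_true(is.na(tr$mean_z_G[nrow(tr)]))
  # plateau: while the community matches the planted module, mean z is flat
  mod <- names(b$structure$fine_labels)[b$structure$fine_labels ==
                                          b$structure$fine_labels[[p]]]
  match_rows <- vapply(seq_len(nrow(tr)), function(g) {
    memb <- sweep_partition(sw, tr$log_lambda[g])
    setequal(names(memb)[memb == memb[[p]]], mod)
  }, TRUE)
  if (sum(match_rows) >= 2) {
    expect_equal(diff(range(tr$mean_z_G[match_rows])), 0, tolerance = 1e-9)
  }
  expect_error(trace_protein(sw, b$network, "absent"), "unknown protein")
})
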