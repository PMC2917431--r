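test_that("planted generator honours edge probabilities and nesting", {
  # p = 1 within a single fine module gives the complete graph
  gen <- generate_planted_network(1, 1, 5, p_fine = 1, p_coarse = 0.5,
                                  p_between = 0, seed = 1)
  expect_equal(igraph::vcount(gen$network), 5)
  expect_equal(igraph::ecount(gen$network), 10)

  # empirical within-fine density over 50 seeds
  dens <- vapply(1:50, function(s) {
    g <- generate_planted_network(2, 2, 8, 0.9, 0.3, 0.02, seed = s,
                                  keep_lcc = FALSE)
    fine <- g$structure$fine_labels
    el <- igraph::as_edgelist(g$network)
    within <- sum(fine[el[, 1]] == fine[el[, 2]])
    within / (4 * choose(8, 2))
  }, 1)
  expect_lt(abs(mean(dens) - 0.9), 0.05)

  # no cross-module edges -> one component per fine module
  g0 <- generate_planted_network(2, 2, 10, p_fine = 0.9, p_coarse = 0,
                                 p_between = 0, seed = 4, keep_lcc = FALSE)
  expect_equal(igraph::components(g0$network)$no, 4)

  # invalid ordering rejected
  expect_error(generate_planted_network(2, 2, 8, p_fine = 0.2,
                                        p_coarse = 0.5, p_between = 0.01),
               "ordering")

  # nesting invariant: each fine module sits in exactly one coarse module
  st <- generate_planted_network(seed = 2)$structure
  expect_true(all(tapply(st$coarse_labels, st$fine_labels,
                         function(x) length(unique(x))) == 1))
})

test_that("Erdos-Renyi generator matches binomial expectations", {
  expect_equal(igraph::ecount(generate_er_network(10, 0, seed = 1)), 0)
  expect_equal(igraph::vcount(generate_er_network(10, 0, seed = 1)), 1)
  expect_equal(igraph::ecount(generate_er_network(10, 1, seed = 1)), 45)
  m <- vapply(1:100, function(s)
    igraph::ecount(generate_er_network(200, 0.05, seed = s,
                                       keep_lcc = FALSE)), 1)
  mu <- 0.05 * choose(200, 2)
  se <- sqrt(choose(200, 2) * 0.05 * 0.95) / sqrt(100)
  expect_lt(abs(mean(m) - mu), 3 * se)
})

test_that("annotation fidelity controls within-module similarity signal", {
  # fidelity 1: identical term sets within each fine module
  gen <- generate_planted_network(2, 2, 10, seed = 3)
  a1 <- generate_annotations(gen$structure, fidelity = 1, seed = 3)
  by_mod <- split(a1$annotations, gen$structure$fine_labels)
  expect_true(all(vapply(by_mod, function(g)
    length(unique(lapply(g, sort))) == 1, TRUE)))

  within_minus_between <- function(fidelity, seed) {
    gen <- generate_planted_network(1, 2, 20, 0.5, 0.05, 0.05,
                                    seed = seed, keep_lcc = FALSE)
    a <- propagate_annotations(generate_annotations(
      gen$structure, fidelity = fidelity, seed = seed + 17L))
    fine <- gen$structure$fine_labels
    prots <- names(fine)
    pairs <- t(combn(prots, 2))
    sims <- vapply(seq_len(nrow(pairs)), function(r)
      go_similarity(a, pairs[r, 1], pairs[r, 2]), 1)
    within <- fine[pairs[, 1]] == fine[pairs[, 2]]
    mean(sims[within]) - mean(sims[!within])
  }

  # fidelity 0: no separation (difference within 2 s.e. over 20 seeds)
  d0 <- vapply(1:20, function(s) within_minus_between(0, s), 1)
  expect_lt(abs(mean(d0)), 2 * sd(d0) / sqrt(length(d0)))

  # fidelity 0.9: within > between in at least 95% of 100 seeds
  d9 <- vapply(1:100, function(s) within_minus_between(0.9, s), 1)
  expect_gte(mean(d9 > 0), 0.95)

  # monotone signal in fidelity at 0, 0.5, 1 (seed-averaged)
  means <- vapply(c(0, 0.5, 1), function(f)
    mean(vapply(1:10, function(s) within_minus_between(f, s), 1)), 1)
  expect_true(all(diff(means) >= 0))
})

test_that("growth profiles carry the planted correlation structure", {
  gen <- generate_planted_network(2, 2, 10, seed = 5)
  st <- gen$structure

  # vanishing noise: within-module correlation approaches 1
  gm <- generate_growth_profiles(st, n_conditions = 50, effect_size = 1,
                                 noise_sd = 1e-6, seed = 1)
  mod1 <- names(st$fine_labels)[st$fine_labels == 1][1:2]
  expect_gt(growth_correlation(gm, mod1[1], mod1[2]), 0.999)

  # zero effect size: mean within-module correlation ~ 0 over 20 seeds
  mw <- vapply(1:20, function(s) {
    gm <- generate_growth_profiles(st, n_conditions = 50, effect_size = 0,
                                   noise_sd = 0.5, seed = s)
    prots <- names(st$fine_labels)[st$fine_labels == 1]
    pairs <- t(combn(prots, 2))
    mean(vapply(seq_len(nrow(pairs)), function(r)
      growth_correlation(gm, pairs[r, 1], pairs[r, 2]), 1))
  }, 1)
  expect_lt(abs(mean(mw)), 3 * sd(mw) / sqrt(length(mw)))

  # missing fraction thins the profiled set binomially
  nprof <- vapply(1:30, function(s)
    nrow(generate_growth_profiles(st, n_conditions = 10,
                                  missing_fraction = 0.3,
                                  seed = s)$profiles), 1)
  expect_true(all(nprof == 28))  # round(0.3 * 40) removed deterministically
})

test_that("generation is reproducible and serialises byte-identically", {
  g1 <- generate_planted_network(seed = 11)
  g2 <- generate_planted_network(seed = 11)
  f1 <- tempfile(); f2 <- tempfile()
  write_edge_tsv(g1$network, f1)
  write_edge_tsv(g2$network, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g1$structure, g2$structure)

  a1 <- generate_annotations(g1$structure, fidelity = 0.7, seed = 5)
  a2 <- generate_annotations(g2$structure, fidelity = 0.7, seed = 5)
  expect_identical(a1$annotations, a2$annotations)

  gm1 <- generate_growth_profiles(g1$structure, n_conditions = 20, seed = 5)
  gm2 <- generate_growth_profiles(g2$structure, n_conditions = 20, seed = 5)
  expect_identical(gm1$profiles, gm2$profiles)

  # generated networks satisfy the container invariants
  el <- igraph::as_edgelist(g1$network)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  expect_false(any(duplicated(key)))
})

test_that("file writers round-trip annotations, ontology and growth", {
  gen <- generate_planted_network(2, 2, 6, seed = 9)
  ann <- generate_annotations(gen$structure, fidelity = 0.8, seed = 9)
  fo <- tempfile(fileext = ".obo")
  fa <- tempfile(fileext = ".tsv")
  write_obo(ann$dag, ann$root, fo)
  write_annotation_tsv(ann, fa)
  ont <- read_obo(fo)
  back <- read_annotation_tsv(fa, ont)
  expect_setequal(names(back$annotations), names(ann$annotations))
  for (p in names(ann$annotations)) {
    expect_setequal(back$annotations[[p]], ann$annotations[[p]])
  }
  expect_identical(sort(names(ont$dag)), sort(names(ann$dag)))

  gm <- generate_growth_profiles(gen$structure, n_conditions = 8, seed = 2)
  fg <- tempfile(fileext = ".csv")
  write_growth_csv(gm, fg, raw = TRUE)  # raw rates exercise the transform
  back_gm <- read_growth_csv(fg, raw = TRUE)
  expect_equal(back_gm$profiles, gm$profiles, tolerance = 1e-12)
})
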