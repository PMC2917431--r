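#' Generate a two-level planted-community benchmark network
#'
#' A hierarchical stochastic block model with two nested levels: each of
#' `n_coarse` coarse modules contains `fine_per_coarse` fine modules of
#' `fine_size` nodes.  Edges are drawn independently with probability
#' `p_fine` within a fine module, `p_coarse` between fine modules of the
#' same coarse module, and `p_between` otherwise, and the largest connected
#' component is returned (with ground-truth labels restricted to it).  The
#' defaults are the benchmark conditions used throughout the package's
#' validation: 4 coarse x 3 fine x 15 nodes with p = 0.6 / 0.15 / 0.01, a
#' network with strong communities at two well-separated scales.
#'
#' @param n_coarse Number of coarse modules.
#' @param fine_per_coarse Fine modules per coarse module.
#' @param fine_size Nodes per fine module.
#' @param p_fine,p_coarse,p_between Edge probabilities; must satisfy
#'   `p_fine > p_coarse >= p_between >= 0`.
#' @param seed Integer seed; generation is fully reproducible.
#' @param keep_lcc Return only the largest connected component (default);
#'   `FALSE` returns the full graph (useful to count components when
#'   `p_between = 0`).
#' @return A list: `network` (`igraph`, vertices named `p001`, ...) and
#'   `structure`, an object of class `"planted_structure"` with named
#'   integer vectors `fine_labels` and `coarse_labels` over the returned
#'   nodes plus the generator `params`.
#' @export
generate_planted_network <- function(n_coarse = 4, fine_per_coarse = 3,
                                     fine_size = 15, p_fine = 0.6,
                                     p_coarse = 0.15, p_between = 0.01,
                                     seed = 1L, keep_lcc = TRUE) {
  stopifnot(n_coarse >= 1, fine_per_coarse >= 1, fine_size >= 1)
  if (!(p_fine > p_coarse || (n_coarse * fine_per_coarse == 1)) ||
      p_coarse < p_between || p_between < 0 || p_fine > 1) {
    stop("invalid probability ordering: need p_fine > p_coarse >= ",
         "p_between >= 0")
  }
  n_fine <- n_coarse * fine_per_coarse
  n <- n_fine * fine_size
  fine <- rep(seq_len(n_fine), each = fine_size)
  coarse <- (fine - 1L) %/% fine_per_coarse + 1L
  pref <- matrix(p_between, n_fine, n_fine)
  cf <- (seq_len(n_fine) - 1L) %/% fine_per_coarse
  pref[outer(cf, cf, "==")] <- p_coarse
  diag(pref) <- p_fine
  withr::local_seed(seed)
  g <- igraph::sample_sbm(n, pref.matrix = pref,
                          block.sizes = rep(fine_size, n_fine))
  igraph::V(g)$name <- sprintf("p%03d", seq_len(n))
  names(fine) <- names(coarse) <- igraph::V(g)$name
  if (keep_lcc) {
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
    keep <- igraph::V(g)$name
    fine <- fine[keep]
    coarse <- coarse[keep]
  }
  structure_obj <- structure(
    list(fine_labels = fine, coarse_labels = coarse,
         params = list(n_coarse = n_coarse,
                       fine_per_coarse = fine_per_coarse,
                       fine_size = fine_size, p_fine = p_fine,
                       p_coarse = p_coarse, p_between = p_between,
                       seed = seed)),
    class = "planted_structure")
  list(network = g, structure = structure_obj)
}

#' @export
print.planted_structure <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Planted structure: %d coarse x %d fine x %d nodes (%d retained)\n",
    p$n_coarse, p$fine_per_coarse, p$fine_size, length(x$fine_labels)))
  cat(sprintf("  p_fine = %g, p_coarse = %g, p_between = %g, seed = %s\n",
              p$p_fine, p$p_coarse, p$p_between, format(p$seed)))
  invisible(x)
}

#' Generate an Erdos-Renyi reference network
#'
#' A G(n, p) random graph, restricted to its largest connected component —
#' the structureless reference against which planted-community behaviour
#' is contrasted.  At `p = 0` the LCC is a single (arbitrary, the first)
#' node.
#'
#' @param n Number of nodes.
#' @param p Edge probability in \[0, 1\].
#' @param seed Integer seed.
#' @param keep_lcc Restrict to the largest connected component (default).
#' @return An `igraph` network with named vertices.
#' @export
generate_er_network <- function(n, p, seed = 1L, keep_lcc = TRUE) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  withr::local_seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("p%03d", seq_len(n))
  if (keep_lcc) {
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  }
  g
}

#' Generate synthetic annotations with tunable fidelity
#'
#' Builds a three-level rooted term tree — root, one branch term per coarse
#' module, one leaf-term set (`terms_per_module` terms) per fine module —
#' plus `n_background_terms` background terms directly under the root.
#' Each protein receives its own fine module's leaf-term set with
#' probability `fidelity`, and otherwise a single random background term
#' (so unannotated-pair semantics stay exercised: background-annotated
#' pairs almost never share a rare set).  At `fidelity = 1` every member of
#' a fine module carries an identical rare term set; at `fidelity = 0` the
#' annotations carry no module signal at all.
#'
#' @param structure A `"planted_structure"`.
#' @param terms_per_module Leaf terms per fine module (default 3).
#' @param n_background_terms Background terms under the root (default 20).
#' @param fidelity Probability a protein is annotated with its module's
#'   term set.
#' @param seed Integer seed.
#' @return A raw (unpropagated) `"annotation_set"`; pass through
#'   [propagate_annotations()] before computing similarities.
#' @export
generate_annotations <- function(structure, terms_per_module = 3,
                                 n_background_terms = 20, fidelity,
                                 seed = 1L) {
  stopifnot(inherits(structure, "planted_structure"),
            fidelity >= 0, fidelity <= 1, terms_per_module >= 1,
            n_background_terms >= 1)
  fine <- structure$fine_labels
  coarse <- structure$coarse_labels
  root <- "T:root"
  dag <- list()
  dag[[root]] <- character(0)
  for (cm in sort(unique(coarse))) {
    dag[[sprintf("T:c%02d", cm)]] <- root
  }
  coarse_of_fine <- tapply(coarse, fine, function(x) x[[1]])
  leaf_sets <- list()
  for (fm in sort(unique(fine))) {
    leaves <- sprintf("T:c%02d.f%02d.%02d", coarse_of_fine[[as.character(fm)]],
                      fm, seq_len(terms_per_module))
    for (lf in leaves) {
      dag[[lf]] <- sprintf("T:c%02d", coarse_of_fine[[as.character(fm)]])
    }
    leaf_sets[[as.character(fm)]] <- leaves
  }
  bg <- sprintf("T:bg%03d", seq_len(n_background_terms))
  for (b in bg) dag[[b]] <- root

  withr::local_seed(seed)
  faithful <- runif(length(fine)) < fidelity
  ann <- vector("list", length(fine))
  names(ann) <- names(fine)
  bg_pick <- sample(bg, length(fine), replace = TRUE)
  for (i in seq_along(fine)) {
    ann[[i]] <- if (faithful[[i]]) {
      leaf_sets[[as.character(fine[[i]])]]
    } else {
      bg_pick[[i]]
    }
  }
  annotation_set(ann, dag, root)
}

#' Generate synthetic knock-out growth profiles
#'
#' Each fine module gets a latent standard-normal condition-response
#' vector; a profiled protein's log-ratio profile is
#' `effect_size * module_vector + noise`, with independent Gaussian noise
#' of s.d. `noise_sd` per condition.  A `missing_fraction` of proteins is
#' left unprofiled, mirroring screens where many deletions are lethal or
#' unmeasured.  Profiles are generated directly on the log-ratio scale;
#' [write_growth_csv()] with `raw = TRUE` converts to raw rates
#' (`control_mean * 2^L`) to exercise the log-ratio transform on read.
#'
#' @param structure A `"planted_structure"`.
#' @param n_conditions Number of treatment conditions (default 418).
#' @param effect_size Scale of the shared module response.
#' @param noise_sd Per-condition noise s.d. (> 0).
#' @param missing_fraction Fraction of proteins without profiles
#'   (\[0, 1)).
#' @param seed Integer seed.
#' @return A `"growth_matrix"` over the profiled proteins, with positive
#'   control means drawn uniformly from \[0.5, 1.5\].
#' @export
generate_growth_profiles <- function(structure, n_conditions = 418,
                                     effect_size = 1, noise_sd = 0.5,
                                     missing_fraction = 0, seed = 1L) {
  stopifnot(inherits(structure, "planted_structure"), noise_sd > 0,
            missing_fraction >= 0, missing_fraction < 1, n_conditions >= 2)
  fine <- structure$fine_labels
  withr::local_seed(seed)
  mods <- sort(unique(fine))
  latent <- matrix(rnorm(length(mods) * n_conditions), length(mods),
                   dimnames = list(mods, NULL))
  n <- length(fine)
  profiled <- rep(TRUE, n)
  n_missing <- round(missing_fraction * n)
  if (n_missing > 0) profiled[sample.int(n, n_missing)] <- FALSE
  prof_names <- names(fine)[profiled]
  L <- effect_size * latent[as.character(fine[profiled]), , drop = FALSE] +
    matrix(rnorm(length(prof_names) * n_conditions, sd = noise_sd),
           length(prof_names))
  dimnames(L) <- list(prof_names, paste0("condition_", seq_len(n_conditions)))
  cm <- setNames(runif(length(prof_names), 0.5, 1.5), prof_names)
  growth_matrix(L, cm)
}

#' Generate a mixed homogeneous/random-community benchmark
#'
#' Joins a two-level planted-community network (functionally coherent,
#' densely wired modules) with an Erdos-Renyi region of the same order
#' (structureless, sparse) through a handful of random bridge edges, and
#' annotates planted proteins through [generate_annotations()] while
#' random-region proteins receive only background terms.  Communities
#' recovered inside the planted part are dense and functionally
#' homogeneous; communities carved out of the random part are sparse and
#' incoherent — the contrast a topological predictor of homogeneity must
#' exploit.
#'
#' @param n_coarse,fine_per_coarse,fine_size,p_fine,p_coarse,p_between
#'   Planted-part parameters (defaults 2 x 3 x 12, p = 0.6/0.15/0.01).
#' @param n_er,p_er Random-part size and edge probability (defaults 72,
#'   0.06 — mean degree comparable to sparse interaction data).
#' @param n_bridges Random planted-to-random bridge edges (default 6).
#' @param fidelity Annotation fidelity of the planted part.
#' @param terms_per_module,n_background_terms Passed to
#'   [generate_annotations()].
#' @param seed Integer seed.
#' @return A list: `network` (LCC of the joined graph), `structure`
#'   (planted part), `annotations` (raw `"annotation_set"` over all
#'   retained proteins).
#' @export
generate_mixed_benchmark <- function(n_coarse = 2, fine_per_coarse = 3,
                                     fine_size = 12, p_fine = 0.6,
                                     p_coarse = 0.15, p_between = 0.01,
                                     n_er = 72, p_er = 0.06,
                                     n_bridges = 6, fidelity = 0.9,
                                     terms_per_module = 3,
                                     n_background_terms = 20, seed = 1L) {
  planted <- generate_planted_network(n_coarse, fine_per_coarse, fine_size,
                                      p_fine, p_coarse, p_between,
                                      seed = seed, keep_lcc = FALSE)
  er <- generate_er_network(n_er, p_er, seed = seed + 1L, keep_lcc = FALSE)
  igraph::V(er)$name <- sprintf("r%03d", seq_len(n_er))
  g <- igraph::disjoint_union(planted$network, er)
  withr::local_seed(seed + 2L)
  pn <- igraph::V(planted$network)$name
  rn <- sprintf("r%03d", seq_len(n_er))
  bridges <- cbind(sample(pn, n_bridges, replace = TRUE),
                   sample(rn, n_bridges, replace = TRUE))
  g <- igraph::add_edges(g, t(bridges))
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership ==
                                           which.max(comp$csize)))
  keep <- igraph::V(g)$name
  st <- planted$structure
  st$fine_labels <- st$fine_labels[intersect(names(st$fine_labels), keep)]
  st$coarse_labels <- st$coarse_labels[names(st$fine_labels)]
  ann <- generate_annotations(planted$structure, terms_per_module,
                              n_background_terms, fidelity,
                              seed = seed + 3L)
  bg <- grep("^T:bg", names(ann$dag), value = TRUE)
  extra <- setNames(as.list(sample(bg, length(rn), replace = TRUE)), rn)
  ann$annotations <- c(ann$annotations, extra)
  ann$annotations <- ann$annotations[intersect(names(ann$annotations), keep)]
  list(network = g, structure = st, annotations = ann)
}

#' Write ground-truth module labels as CSV
#'
#' Columns `protein`, `fine_label`, `coarse_label`.
#'
#' @param structure A `"planted_structure"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(structure, path) {
  df <- data.frame(protein = names(structure$fine_labels),
                   fine_label = as.integer(structure$fine_labels),
                   coarse_label = as.integer(structure$coarse_labels))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
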