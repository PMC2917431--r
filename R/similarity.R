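#' Construct an annotation set
#'
#' Bundles protein-to-term annotations with the term ontology they come
#' from.  The ontology is a rooted directed acyclic graph given as a
#' parent-list; a flat vocabulary is the special case where every term's
#' only parent is the root.
#'
#' @param annotations Named list: protein id -> character vector of term ids
#'   (the most specific terms known for that protein).
#' @param dag Named list: term id -> character vector of parent term ids.
#'   Every term must reach `root`.
#' @param root Root term id.
#' @return An object of class `"annotation_set"`.
#' @export
annotation_set <- function(annotations, dag, root) {
  stopifnot(is.list(annotations), is.list(dag), is.character(root))
  structure(list(annotations = annotations, dag = dag, root = root,
                 propagated = FALSE),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d proteins, %d terms (root %s), %s\n",
              length(x$annotations), length(x$dag), x$root,
              if (x$propagated) "propagated" else "raw"))
  invisible(x)
}

#' Propagate annotations up the ontology
#'
#' Proteins are annotated with their most specific terms; similarity is
#' computed on the ancestral closure, obtained by following the parent
#' structure of the DAG up to (but excluding) the root.  A protein whose
#' closure is empty — annotated only with the root — counts as unannotated.
#' Propagation is idempotent.
#'
#' @param ann An `"annotation_set"`.
#' @return The annotation set with each protein's terms replaced by their
#'   ancestral closure minus the root, and `propagated = TRUE`.
#' @export
propagate_annotations <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (isTRUE(ann$propagated)) return(ann)
  anc <- ancestor_closure(ann$dag, ann$root)
  ann$annotations <- lapply(ann$annotations, function(terms) {
    terms <- setdiff(terms, ann$root)
    if (!length(terms)) return(character(0))
    unknown <- setdiff(terms, names(anc))
    if (length(unknown)) {
      stop("terms not in ontology: ", paste(unknown, collapse = ", "))
    }
    sort(unique(c(terms, unlist(anc[terms], use.names = FALSE))))
  })
  ann$propagated <- TRUE
  ann
}

# internal: per-term ancestor sets (excluding the root), cycle-checked
ancestor_closure <- function(dag, root) {
  terms <- names(dag)
  anc <- vector("list", length(terms))
  names(anc) <- terms
  state <- setNames(integer(length(terms)), terms)  # 0 new, 1 open, 2 done
  visit <- function(t) {
    if (t == root) return(character(0))
    if (state[[t]] == 1L) stop("cycle detected in ontology at term ", t)
    if (state[[t]] == 2L) return(anc[[t]])
    state[[t]] <<- 1L
    parents <- setdiff(dag[[t]], root)
    up <- character(0)
    for (p in parents) {
      if (!p %in% terms) stop("parent term not in ontology: ", p)
      up <- c(up, p, visit(p))
    }
    anc[[t]] <<- sort(unique(up))
    state[[t]] <<- 2L
    anc[[t]]
  }
  for (t in terms) if (t != root) visit(t)
  anc
}

#' Number of proteins sharing a pair's common term set
#'
#' For proteins `i` and `j`, `n_ij` is the number of proteins in the
#' annotation universe whose (propagated) term set contains every term of
#' the intersection of the two proteins' sets.  An empty intersection is
#' shared vacuously by all `N` proteins, so `n_ij = N`; rarity of the shared
#' set is what makes a pair functionally similar.
#'
#' @param ann A propagated `"annotation_set"` (or a plain named list of term
#'   vectors for a flat vocabulary).
#' @param i,j Protein identifiers.
#' @return The count `n_ij`.
#' @export
shared_set_count <- function(ann, i, j) {
  sets <- annotation_list(ann)
  if (!i %in% names(sets)) stop("unknown protein: ", i)
  if (!j %in% names(sets)) stop("unknown protein: ", j)
  common <- intersect(sets[[i]], sets[[j]])
  if (!length(common)) return(length(sets))
  idx <- annotation_index(ann)
  count_supersets(idx, common)
}

# internal: accept annotation_set or plain list
annotation_list <- function(ann) {
  if (inherits(ann, "annotation_set")) {
    if (!isTRUE(ann$propagated)) {
      stop("annotations must be propagated first (see propagate_annotations)")
    }
    ann$annotations
  } else if (is.list(ann)) {
    ann
  } else {
    stop("expected an annotation_set or a named list of term vectors")
  }
}

# internal: logical protein x term incidence matrix, cached on the object
annotation_index <- function(ann) {
  sets <- annotation_list(ann)
  cached <- attr(ann, "pottsnet_index")
  if (!is.null(cached)) return(cached)
  terms <- sort(unique(unlist(sets, use.names = FALSE)))
  m <- matrix(FALSE, length(sets), length(terms),
              dimnames = list(names(sets), terms))
  for (p in seq_along(sets)) m[p, sets[[p]]] <- TRUE
  m
}

# internal: proteins whose set contains all `terms`, via the index
count_supersets <- function(index, terms) {
  terms <- terms[terms %in% colnames(index)]
  # a term annotated to no protein cannot be contained in any set
  if (length(terms) == 0L) return(0L)
  sum(rowSums(index[, terms, drop = FALSE]) == length(terms))
}

#' Shared-annotation-rarity similarity (ontology form, `G`)
#'
#' \eqn{G_{ij} = 1 - n_{ij}/N}: two proteins are similar when the term set
#' they share is rare in the annotation universe.  The measure is symmetric,
#' lies in \[0, 1\], is 0 when the shared set is vacuous (`n_ij = N`, which
#' covers pairs with an unannotated member — lack of annotation is never
#' penalised beyond similarity 0), and approaches 1 when only the pair
#' itself shares its terms in a large universe.  The functional form is
#' pluggable through `form`; any monotone decreasing function of `n_ij`
#' yields the same downstream homogeneity ordering up to renormalisation.
#'
#' @param ann A propagated `"annotation_set"`.
#' @param i,j Protein identifiers.
#' @param N Total proteins in the annotation universe (defaults to the
#'   number of annotated-universe proteins in `ann`).
#' @param form Function of `(n, N)`; default `1 - n/N`.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' dag <- list(root = character(), t1 = "root", t2 = "t1", t3 = "root")
#' ann <- annotation_set(list(p1 = c("t1", "t2"), p2 = c("t1", "t2"),
#'                            p3 = "t1", p4 = "t3", p5 = character()),
#'                       dag, root = "root")
#' ann <- propagate_annotations(ann)
#' go_similarity(ann, "p1", "p2")  # n = 2 of N = 5 share {t1,t2}: 0.6
go_similarity <- function(ann, i, j, N = NULL,
                          form = function(n, N) 1 - n / N) {
  sets <- annotation_list(ann)
  if (is.null(N)) N <- length(sets)
  if (N < 1) stop("N must be at least 1")
  n_ij <- shared_set_count(ann, i, j)
  form(n_ij, N)
}

#' Shared-annotation-rarity similarity over a flat vocabulary (`M`)
#'
#' The same rarity similarity as [go_similarity()] applied to a flat,
#' single-level vocabulary (for example only the top level of a functional
#' catalogue), so no DAG propagation is involved.
#'
#' @param flat_ann Named list: protein -> character vector of top-level
#'   terms.
#' @param i,j Protein identifiers.
#' @param N Universe size (defaults to `length(flat_ann)`).
#' @param form As in [go_similarity()].
#' @return Similarity in \[0, 1\].
#' @export
flat_similarity <- function(flat_ann, i, j, N = NULL,
                            form = function(n, N) 1 - n / N) {
  go_similarity(flat_ann, i, j, N = N, form = form)
}

#' Construct a growth-profile matrix
#'
#' Knock-out growth screens report, for each deletion strain, growth rates
#' across many treatment conditions plus a per-strain control mean.  The
#' per-condition log-ratio \eqn{L_{i,t} = \log_2(g_{i,t} / \bar g_i)}
#' (with \eqn{\bar g_i} the control mean) is the quantity correlated between
#' strains.
#'
#' @param profiles Numeric matrix of log-ratios, rows = proteins (named),
#'   columns = conditions.
#' @param control_mean Named positive numeric vector of per-strain control
#'   means (defaults to 1 for every profiled strain, i.e. profiles already
#'   on the log-ratio scale with no raw-rate provenance).
#' @return An object of class `"growth_matrix"`.
#' @export
growth_matrix <- function(profiles, control_mean = NULL) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  if (is.null(control_mean)) {
    control_mean <- setNames(rep(1, nrow(profiles)), rownames(profiles))
  }
  stopifnot(all(control_mean > 0))
  structure(list(profiles = profiles,
                 control_mean = control_mean[rownames(profiles)]),
            class = "growth_matrix")
}

#' @export
print.growth_matrix <- function(x, ...) {
  cat(sprintf("Growth matrix: %d profiled strains x %d conditions\n",
              nrow(x$profiles), ncol(x$profiles)))
  invisible(x)
}

#' Correlated-growth similarity (`C`)
#'
#' Pearson correlation of the two strains' log-ratio profiles across
#' conditions.  The log base cancels in the correlation, so only the
#' ratio-to-control structure matters.
#'
#' @param gm A `"growth_matrix"`.
#' @param i,j Protein identifiers; both must be profiled.
#' @return Correlation in \[-1, 1\], or `NA` if either profile has zero
#'   variance.
#' @export
growth_correlation <- function(gm, i, j) {
  stopifnot(inherits(gm, "growth_matrix"))
  if (!i %in% rownames(gm$profiles)) stop("no growth profile for ", i)
  if (!j %in% rownames(gm$profiles)) stop("no growth profile for ", j)
  li <- gm$profiles[i, ]
  lj <- gm$profiles[j, ]
  if (sd(li) == 0 || sd(lj) == 0) return(NA_real_)
  cor(li, lj)
}

#' Similarity values on a network's interacting pairs
#'
#' Evaluates one similarity measure on every edge of the network whose two
#' endpoints have data for that measure, and contrasts the interacting-pair
#' mean with the mean over a uniform random sample of all node pairs (the
#' standard check that interacting pairs are more similar than random
#' pairs).
#'
#' Coverage conventions follow the measures: for `G`/`M` every protein in
#' the annotation universe is covered (an unannotated member just gives
#' similarity 0), while pairs lacking a growth profile are dropped from the
#' `C` edge set.
#'
#' @param net An `igraph` network (self-loops ignored).
#' @param measure `"G"`, `"M"`, or `"C"`.
#' @param data A propagated `"annotation_set"` (`G`), a flat annotation list
#'   (`M`), or a `"growth_matrix"` (`C`).
#' @param all_pairs_sample Number of random node pairs for the all-pairs
#'   summary (0 to skip); sampled without replacement among covered pairs.
#' @param seed Seed for the all-pairs sample.
#' @return An object of class `"edge_similarity"`: `measure`, `values`
#'   (data.frame `protein_a`, `protein_b`, `value`), `coverage` (covered
#'   proteins), `mean_interacting`, `mean_all_pairs`.
#' @export
edge_similarity <- function(net, measure = c("G", "M", "C"), data,
                            all_pairs_sample = 2000, seed = 1L) {
  measure <- match.arg(measure)
  net <- drop_loops(net)
  nodes <- igraph::V(net)$name
  el <- igraph::as_edgelist(net)

  if (measure %in% c("G", "M")) {
    sets <- annotation_list(data)
    covered <- intersect(nodes, names(sets))
    # inline the rarity similarity against a precomputed incidence index
    idx <- annotation_index(data)
    N <- length(sets)
    pair_fun <- function(i, j) {
      common <- intersect(sets[[i]], sets[[j]])
      n_ij <- if (!length(common)) N else count_supersets(idx, common)
      1 - n_ij / N
    }
  } else {
    stopifnot(inherits(data, "growth_matrix"))
    ok <- rownames(data$profiles)[apply(data$profiles, 1, sd) > 0]
    covered <- intersect(nodes, ok)
    prof <- t(data$profiles[covered, , drop = FALSE])
    pair_fun <- function(i, j) cor(prof[, i], prof[, j])
  }

  keep <- el[, 1] %in% covered & el[, 2] %in% covered
  ea <- pmin(el[keep, 1], el[keep, 2])
  eb <- pmax(el[keep, 1], el[keep, 2])
  vals <- if (length(ea)) {
    mapply(pair_fun, ea, eb, USE.NAMES = FALSE)
  } else {
    numeric(0)
  }

  mean_all <- NA_real_
  if (all_pairs_sample > 0 && length(covered) >= 2) {
    withr::local_seed(seed)
    n_possible <- choose(length(covered), 2)
    n_s <- min(all_pairs_sample, n_possible)
    picked <- sample.int(n_possible, n_s)
    pr <- unrank_pairs(picked, length(covered))
    mean_all <- mean(mapply(function(a, b) pair_fun(covered[a], covered[b]),
                            pr[, 1], pr[, 2]))
  }

  structure(list(measure = measure,
                 values = data.frame(protein_a = ea, protein_b = eb,
                                     value = vals),
                 coverage = covered,
                 mean_interacting = if (length(vals)) mean(vals) else NA_real_,
                 mean_all_pairs = mean_all),
            class = "edge_similarity")
}

# internal: k-th unordered pair (1-based, lexicographic) among n items
unrank_pairs <- function(ks, n) {
  # pair (i, j), i < j; index = (i-1)*n - i*(i+1)/2 + j
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * ks))
  j <- ks - ((i - 1) * n - i * (i + 1) / 2)
  cbind(as.integer(i), as.integer(j))
}

#' @export
print.edge_similarity <- function(x, ...) {
  cat(sprintf(
    "Edge similarity (%s): %d scored pairs, %d covered proteins\n",
    x$measure, nrow(x$values), length(x$coverage)))
  cat(sprintf("  mean interacting = %.4f, mean all-pairs sample = %.4f\n",
              x$mean_interacting, x$mean_all_pairs))
  invisible(x)
}
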