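#' Default evidence-code to interaction-type mapping
#'
#' Interaction databases record the experimental evidence behind each pair.
#' Two broad interaction classes are distinguished: physical associations
#' (`"P"`, dominated by yeast-two-hybrid style evidence) and associations
#' (`"A"`, dominated by tandem-affinity-purification style evidence).  This
#' table seeds the classification: BioGrid-style codes (reconstituted
#' complex, PCA, co-crystal structure, yeast-two-hybrid give `P`; affinity
#' capture, biochemical activity, co-fractionation, co-purification, Far
#' Western give `A`) and Mint-style detection categories (biophysical and
#' protein complementation assay give `P`; biochemical gives `A`).
#'
#' Database dialects drift, so the same table is also shipped as an editable
#' CSV in `system.file("extdata", "evidence_map.csv", package = "pottsnet")`;
#' pass any named vector to [read_interactions()] to override.  Matching is
#' case-insensitive on the exact (trimmed) evidence string.
#'
#' @return Named character vector mapping lower-case evidence code to
#'   `"A"` or `"P"`.
#' @export
#' @examples
#' default_evidence_map()[["yeast-two-hybrid"]]
default_evidence_map <- function() {
  c(
    # BioGrid evidence codes
    "reconstituted complex"          = "P",
    "pca"                            = "P",
    "co-crystal structure"           = "P",
    "yeast-two-hybrid"               = "P",
    "affinity capture"               = "A",
    "biochemical activity"           = "A",
    "co-fractionation"               = "A",
    "co-purification"                = "A",
    "far western"                    = "A",
    # Mint detection-type categories
    "biophysical"                    = "P",
    "protein complementation assay"  = "P",
    "biochemical"                    = "A"
  )
}

#' Read interaction records from edge-list TSV files
#'
#' Files are tab-separated with five columns: `protein_a`, `protein_b`,
#' `interaction_type`, `source`, `evidence` (a header line is detected and
#' skipped if its first field is `protein_a`).  The interaction type of each
#' record is resolved from its evidence code through `evidence_map`, not
#' taken from the file's type column, so that typing is consistent across
#' source databases.
#'
#' @param paths Character vector of file paths.
#' @param evidence_map Named character vector mapping (lower-case) evidence
#'   codes to `"A"`/`"P"`; defaults to [default_evidence_map()].
#' @param on_unmapped `"fail"` (default) stops on the first unmapped
#'   evidence code; `"skip"` drops such records with a warning listing the
#'   codes encountered.
#' @return A data.frame with columns `protein_a`, `protein_b`, `itype`,
#'   `source`, `evidence`.  Unmapped codes that were skipped are attached as
#'   `attr(, "unmapped_codes")`.
#' @export
read_interactions <- function(paths, evidence_map = default_evidence_map(),
                              on_unmapped = c("fail", "skip")) {
  on_unmapped <- match.arg(on_unmapped)
  names(evidence_map) <- tolower(trimws(names(evidence_map)))
  out <- vector("list", length(paths))
  for (f in seq_along(paths)) {
    lines <- readLines(paths[[f]])
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) && startsWith(lines[[1]], "protein_a")) {
      lines <- lines[-1]
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 1L) != 5L)
    if (length(bad)) {
      stop(sprintf("malformed line %d in %s: expected 5 tab-separated fields",
                   bad[[1]], paths[[f]]))
    }
    m <- do.call(rbind, fields)
    rec <- data.frame(protein_a = trimws(m[, 1]), protein_b = trimws(m[, 2]),
                      source = trimws(m[, 4]), evidence = trimws(m[, 5]),
                      stringsAsFactors = FALSE)
    if (any(!nzchar(rec$protein_a)) || any(!nzchar(rec$protein_b))) {
      stop(sprintf("empty protein identifier in %s", paths[[f]]))
    }
    out[[f]] <- rec
  }
  rec <- do.call(rbind, out)
  key <- tolower(rec$evidence)
  rec$itype <- unname(evidence_map[key])
  unmapped <- sort(unique(rec$evidence[is.na(rec$itype)]))
  if (length(unmapped)) {
    msg <- paste0("unmapped evidence codes: ", paste(unmapped, collapse = ", "))
    if (on_unmapped == "fail") stop(msg)
    warning(msg, "; records skipped")
    rec <- rec[!is.na(rec$itype), , drop = FALSE]
  }
  rec <- rec[, c("protein_a", "protein_b", "itype", "source", "evidence")]
  rownames(rec) <- NULL
  attr(rec, "unmapped_codes") <- unmapped
  rec
}

#' Assemble an interaction network of one type
#'
#' Filters records to the requested interaction type, merges them across
#' sources, collapses duplicate pairs in either orientation, and optionally
#' restricts to the largest connected component.  Self-interactions are kept
#' as self-loop edges (they appear in summary statistics) but are ignored
#' when determining connectivity, and downstream community detection drops
#' them — a self-pair's energy contribution is the same in every partition,
#' so this cannot change any optimum.
#'
#' @param records Data.frame as returned by [read_interactions()], or any
#'   data.frame with columns `protein_a`, `protein_b` and (if `itype` is not
#'   `NULL`) `itype`.
#' @param itype `"A"`, `"P"`, or `NULL` to use all records.
#' @param keep_lcc Keep only the largest connected component (default TRUE).
#' @return An undirected `igraph` graph with named vertices; duplicate edges
#'   removed, self-loops retained.
#' @export
build_network <- function(records, itype = NULL, keep_lcc = TRUE) {
  if (!is.null(itype)) {
    records <- records[records$itype == itype, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop("no interaction records", if (!is.null(itype))
      sprintf(" of type %s", itype) else "", " to build a network from")
  }
  a <- as.character(records$protein_a)
  b <- as.character(records$protein_b)
  # canonical orientation, then dedupe
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  g <- igraph::graph_from_edgelist(cbind(lo[keep], hi[keep]), directed = FALSE)
  if (keep_lcc) {
    gl <- igraph::delete_edges(g, which(igraph::which_loop(g)))
    comp <- igraph::components(gl)
    biggest <- which.max(comp$csize)
    g <- igraph::induced_subgraph(g, which(comp$membership == biggest))
  }
  g
}

#' Summary statistics of an interaction network
#'
#' Degree counts a self-loop twice, so `mean_degree = 2 W / n` with `W` the
#' edge count (self-loops counted once).  The mean clustering coefficient is
#' the average over all nodes of the per-node triangle/triple ratio
#' ([node_clustering()]), with self-loops ignored and nodes of degree < 2
#' contributing 0.
#'
#' @param net An `igraph` network.
#' @return A one-row data.frame: `n_nodes`, `n_edges`, `n_self_edges`,
#'   `mean_degree`, `mean_clustering`.
#' @export
network_summary <- function(net) {
  n <- igraph::vcount(net)
  w <- igraph::ecount(net)
  nself <- sum(igraph::which_loop(net))
  gs <- drop_loops(net)
  cc <- local_clustering(gs)
  data.frame(n_nodes = n, n_edges = w, n_self_edges = nself,
             mean_degree = 2 * w / n, mean_clustering = mean(cc))
}

#' Write a network as a canonical edge-list TSV
#'
#' Two columns `protein_a`, `protein_b`, each edge once in canonical (sorted)
#' orientation.  [read_edge_tsv()] round-trips it.
#'
#' @param net An `igraph` network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(protein_a = pmin(el[, 1], el[, 2]),
                   protein_b = pmax(el[, 1], el[, 2]))
  df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("protein_a\tprotein_b", con)
  writeLines(paste(df$protein_a, df$protein_b, sep = "\t"), con)
  invisible(path)
}

#' Read a two-column edge-list TSV written by [write_edge_tsv()]
#'
#' @param path File path.
#' @param keep_lcc Restrict to the largest connected component.
#' @return An `igraph` network.
#' @export
read_edge_tsv <- function(path, keep_lcc = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  build_network(df, itype = NULL, keep_lcc = keep_lcc)
}

# internal: remove self-loops
drop_loops <- function(net) {
  loops <- which(igraph::which_loop(net))
  if (length(loops)) igraph::delete_edges(net, loops) else net
}
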