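#' Write an ontology in minimal OBO format
#'
#' Emits `[Term]` stanzas with `id:` and `is_a:` lines only — the subset of
#' OBO needed to round-trip the term DAG.
#'
#' @param dag Named list: term -> character vector of parents.
#' @param root Root term id.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, root, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in names(dag)) {
    writeLines(c("[Term]", paste0("id: ", t)), con)
    for (p in dag[[t]]) writeLines(paste0("is_a: ", p), con)
    writeLines("", con)
  }
  writeLines(paste0("! root: ", root), con)
  invisible(path)
}

#' Read a minimal OBO ontology
#'
#' Parses `[Term]` stanzas, keeping `id:` and `is_a:` fields.  The root is
#' taken as the unique term without parents (or from the trailing root
#' comment written by [write_obo()]).
#'
#' @param path OBO file path.
#' @return List with elements `dag` (term -> parents) and `root`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  dag <- list()
  cur <- NULL
  root_hint <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      cur <- NULL
    } else if (startsWith(ln, "id: ")) {
      cur <- sub("^id: ", "", ln)
      # strip a trailing name qualifier if present ("id: X ! name")
      cur <- trimws(sub(" !.*$", "", cur))
      if (is.null(dag[[cur]])) dag[[cur]] <- character(0)
    } else if (startsWith(ln, "is_a: ") && !is.null(cur)) {
      p <- trimws(sub(" !.*$", "", sub("^is_a: ", "", ln)))
      dag[[cur]] <- c(dag[[cur]], p)
    } else if (startsWith(ln, "! root: ")) {
      root_hint <- sub("^! root: ", "", ln)
    }
  }
  roots <- names(dag)[vapply(dag, length, 1L) == 0L]
  root <- if (!is.null(root_hint)) root_hint else {
    if (length(roots) != 1L) {
      stop("ontology must have exactly one root; found: ",
           paste(roots, collapse = ", "))
    }
    roots
  }
  list(dag = dag, root = root)
}

#' Write protein annotations as TSV
#'
#' Two columns `protein`, `term`; one row per annotation.  Unannotated
#' proteins appear with an empty term field so the universe round-trips.
#'
#' @param ann An `"annotation_set"` (raw or propagated).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  rows <- lapply(names(ann$annotations), function(p) {
    terms <- ann$annotations[[p]]
    if (!length(terms)) terms <- ""
    paste(p, terms, sep = "\t")
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("protein\tterm", con)
  writeLines(unlist(rows), con)
  invisible(path)
}

#' Read protein annotations from TSV
#'
#' @param path Annotation TSV (`protein`, `term`).
#' @param ontology List with `dag` and `root` as from [read_obo()].
#' @return A raw `"annotation_set"`.
#' @export
read_annotation_tsv <- function(path, ontology) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character"))
  ann <- tapply(df$term, df$protein, function(x) {
    x <- x[nzchar(x)]
    unique(x)
  }, simplify = FALSE)
  ann <- lapply(ann, function(x) if (is.null(x)) character(0) else x)
  annotation_set(ann, ontology$dag, ontology$root)
}

#' Write growth profiles as CSV
#'
#' One row per profiled strain: `strain`, `control_mean`, then
#' `condition_1..condition_n`.  With `raw = FALSE` (default) conditions
#' hold log-ratios `L`; with `raw = TRUE` they hold raw growth rates
#' `control_mean * 2^L`, so reading back with `raw = TRUE` exercises the
#' log-ratio transform.
#'
#' @param gm A `"growth_matrix"`.
#' @param path Output path.
#' @param raw Write raw rates instead of log-ratios.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(gm, path, raw = FALSE) {
  stopifnot(inherits(gm, "growth_matrix"))
  vals <- if (raw) gm$control_mean * 2^gm$profiles else gm$profiles
  df <- data.frame(strain = rownames(gm$profiles),
                   control_mean = as.numeric(gm$control_mean), vals,
                   check.names = FALSE)
  colnames(df) <- c("strain", "control_mean",
                    paste0("condition_", seq_len(ncol(gm$profiles))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read growth profiles from CSV
#'
#' @param path CSV written by [write_growth_csv()].
#' @param raw If `TRUE`, condition columns are raw rates and are converted
#'   to log-ratios `log2(rate / control_mean)`.
#' @return A `"growth_matrix"`.
#' @export
read_growth_csv <- function(path, raw = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  prof <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(prof) <- df$strain
  cm <- setNames(df$control_mean, df$strain)
  if (raw) prof <- log2(prof / cm)
  growth_matrix(prof, cm)
}
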