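#' Construct a disease DAG
#'
#' A rooted (possibly multi-rooted) directed acyclic graph over disease
#' ontology terms, with edges pointing parent -> child, plus an optional
#' annotation mapping dataset disease identifiers to one or more terms.
#' When no annotation is given, disease identifiers are taken to be terms
#' themselves (identity annotation).
#'
#' @param edges two-column data frame (or matrix) of `parent`, `child` term
#'   ids; may have zero rows.
#' @param terms character vector of term ids; defaults to the ids appearing
#'   in `edges`. Isolated terms may be added here.
#' @param annotation named list: `disease_id -> character vector of term
#'   ids`, or `NULL` for identity annotation.
#' @return Object of class `disease_dag`: list with `terms`, `edges`
#'   (data frame `parent`, `child`), `parents` and `children` adjacency
#'   lists, `annotation`.
#' @export
disease_dag <- function(edges, terms = NULL, annotation = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(parent = as.character(edges[[1]]),
                        child = as.character(edges[[2]]),
                        stringsAsFactors = FALSE)
    edges <- edges[!duplicated(edges), , drop = FALSE]
  }
  if (is.null(terms)) terms <- unique(c(edges$parent, edges$child))
  terms <- unique(as.character(terms))
  if (length(bad <- setdiff(c(edges$parent, edges$child), terms))) {
    stop("edge endpoint not in term set: ", bad[1])
  }
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = terms))
    if (!igraph::is_dag(g)) stop("cycle detected: edges do not form a DAG")
  }
  children <- split(edges$child, factor(edges$parent, levels = terms))
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  # fixed sorted iteration order for reproducibility
  children <- lapply(children, sort)
  parents <- lapply(parents, sort)
  if (!is.null(annotation)) {
    annotation <- lapply(annotation, as.character)
    if (length(bad <- setdiff(unlist(annotation), terms))) {
      stop("annotation maps to unknown term: ", bad[1])
    }
  }
  structure(list(terms = terms, edges = edges, children = children,
                 parents = parents, annotation = annotation),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease_dag: %d terms, %d edges, %s annotation\n",
              length(x$terms), nrow(x$edges),
              if (is.null(x$annotation)) "identity" else
                sprintf("%d-id", length(x$annotation))))
  invisible(x)
}

#' Read a disease DAG from TSV files
#'
#' The edge file holds `parent_id<TAB>child_id` rows (header optional and
#' detected from the literal column names `parent`/`child`); the optional
#' annotation file holds `disease_id<TAB>term_id` rows.
#'
#' @param path edge-list TSV.
#' @param annotation_path optional annotation TSV.
#' @return A [disease_dag()].
#' @export
read_disease_dag <- function(path, annotation_path = NULL) {
  if (!file.exists(path)) stop("DAG file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (nrow(df) > 0 && identical(tolower(df[1, 1]), "parent")) {
    df <- df[-1, , drop = FALSE]
  }
  ann <- NULL
  if (!is.null(annotation_path)) {
    if (!file.exists(annotation_path)) {
      stop("annotation file not found: ", annotation_path)
    }
    a <- utils::read.table(annotation_path, header = FALSE, sep = "\t",
                           colClasses = "character")
    ann <- split(a[[2]], a[[1]])
  }
  disease_dag(df, annotation = ann)
}

#' Write a disease DAG as parent/child TSV
#'
#' @param dag a `disease_dag`.
#' @param path output path for the edge list.
#' @param annotation_path optional output path for the annotation table.
#' @return `path`, invisibly.
#' @export
write_disease_dag <- function(dag, path, annotation_path = NULL) {
  utils::write.table(dag$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(annotation_path) && !is.null(dag$annotation)) {
    a <- data.frame(
      disease_id = rep(names(dag$annotation), lengths(dag$annotation)),
      term_id = unlist(dag$annotation, use.names = FALSE))
    utils::write.table(a, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Term ids for a dataset disease id under the DAG's annotation (identity when
# no annotation is attached). Returns character(0) for unmapped diseases.
dag_terms_for <- function(dag, disease_id) {
  if (is.null(dag$annotation)) {
    if (disease_id %in% dag$terms) disease_id else character(0)
  } else {
    tt <- dag$annotation[[disease_id]]
    if (is.null(tt)) character(0) else tt
  }
}

# Ancestor closure T(D): D together with every term from which D is
# reachable along parent -> child edges.
ancestor_closure <- function(dag, term) {
  seen <- new.env(parent = emptyenv())
  stack <- term
  while (length(stack)) {
    t <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (!is.null(seen[[t]])) next
    seen[[t]] <- TRUE
    stack <- c(stack, dag$parents[[t]])
  }
  ls(seen)
}
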