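#' Semantic contributions of a term's ancestors
#'
#' Computes, for a focus term `D` and every term `d` in its ancestor closure
#' `T(D)`, the decayed semantic contribution: the focus contributes 1 to
#' itself, and each ancestor contributes `delta` times the largest
#' contribution among its children inside `T(D)`, so a term's contribution
#' decays geometrically with its distance from the focus. The semantic value
#' `DV(D)` is the sum of all contributions.
#'
#' @param dag a [disease_dag()].
#' @param term focus term id (must be a DAG term).
#' @param delta decay factor in (0, 1); default 0.5, the conventional value
#'   for MeSH-style disease similarity.
#' @return Object of class `contribution_map`: list with `focus`,
#'   `contributions` (named numeric over `T(D)`), `semantic_value`.
#' @export
semantic_contributions <- function(dag, term, delta = 0.5) {
  if (!is.character(term)) term <- as.character(term)
  if (!(term %in% dag$terms)) stop("term not in DAG: ", term)
  if (!(delta > 0 && delta < 1)) stop("delta must lie in (0, 1)")
  closure <- ancestor_closure(dag, term)
  memo <- new.env(parent = emptyenv())
  memo[[term]] <- 1
  contrib <- function(d) {
    v <- memo[[d]]
    if (!is.null(v)) return(v)
    kids <- intersect(dag$children[[d]], closure)
    # every non-focus member of T(D) lies on a path to the focus, so kids
    # is non-empty for them; acyclicity bounds the recursion
    v <- delta * max(vapply(kids, contrib, numeric(1)))
    memo[[d]] <- v
    v
  }
  vals <- vapply(closure, contrib, numeric(1))
  names(vals) <- closure
  structure(list(focus = term, contributions = vals,
                 semantic_value = sum(vals)),
            class = "contribution_map")
}

#' Semantic similarity between two disease terms
#'
#' Shared-ancestor similarity: the contributions of all terms in
#' `T(d_i) intersect T(d_j)` to each focus are summed and normalized by the
#' two semantic values, giving a symmetric score in `[0, 1]` that is 1 for
#' identical terms and 0 for terms with no common ancestor.
#'
#' @param dag a [disease_dag()].
#' @param term_i,term_j term ids.
#' @inheritParams semantic_contributions
#' @return Similarity in `[0, 1]`.
#' @export
disease_semantic_similarity <- function(dag, term_i, term_j, delta = 0.5) {
  ci <- semantic_contributions(dag, term_i, delta)
  cj <- semantic_contributions(dag, term_j, delta)
  shared <- intersect(names(ci$contributions), names(cj$contributions))
  if (!length(shared)) return(0)
  sum(ci$contributions[shared] + cj$contributions[shared]) /
    (ci$semantic_value + cj$semantic_value)
}

#' Pairwise disease semantic similarity matrix
#'
#' Applies [disease_semantic_similarity()] to every pair of dataset disease
#' identifiers. A disease annotated to several DAG terms scores against
#' another disease as the maximum over all term pairs; a disease with no DAG
#' term gets `NA` off-diagonal (an explicit missing marker, never silently 0)
#' and 1 on the diagonal.
#'
#' @param dag a [disease_dag()].
#' @param disease_ids character vector of dataset disease identifiers.
#' @inheritParams semantic_contributions
#' @return A symmetric numeric matrix with `disease_ids` dimnames,
#'   class `similarity_matrix`.
#' @export
disease_similarity_matrix <- function(dag, disease_ids, delta = 0.5) {
  disease_ids <- as.character(disease_ids)
  if (!length(disease_ids)) stop("empty disease list")
  if (anyDuplicated(disease_ids)) stop("duplicate disease identifiers")
  term_sets <- lapply(disease_ids, dag_terms_for, dag = dag)
  terms <- unique(unlist(term_sets))
  cmaps <- lapply(terms, semantic_contributions, dag = dag, delta = delta)
  names(cmaps) <- terms
  term_ss <- function(a, b) {
    ca <- cmaps[[a]]; cb <- cmaps[[b]]
    shared <- intersect(names(ca$contributions), names(cb$contributions))
    if (!length(shared)) return(0)
    sum(ca$contributions[shared] + cb$contributions[shared]) /
      (ca$semantic_value + cb$semantic_value)
  }
  n <- length(disease_ids)
  S <- matrix(NA_real_, n, n, dimnames = list(disease_ids, disease_ids))
  diag(S) <- 1
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      ti <- term_sets[[i]]
      if (!length(ti)) next
      for (j in seq(i + 1, n)) {
        tj <- term_sets[[j]]
        if (!length(tj)) next
        best <- max(outer(ti, tj, Vectorize(term_ss)))
        S[i, j] <- S[j, i] <- best
      }
    }
  }
  structure(S, class = c("similarity_matrix", class(S)))
}

#' miRNA functional similarity (best-match average)
#'
#' Scores two miRNAs by the semantic similarity of their associated disease
#' sets `D_i`, `D_j` (the columns where each miRNA's row of `Y` is 1): each
#' disease of one set is matched to its most similar disease in the other
#' set, and the matched scores from both directions are averaged:
#' `FS = (sum_{d in D_i} max_{d' in D_j} SS(d, d') +
#'        sum_{d in D_j} max_{d' in D_i} SS(d, d')) / (|D_i| + |D_j|)`.
#'
#' @param dataset an [association_dataset()].
#' @param SS disease similarity matrix indexed by the dataset's disease ids
#'   (from [disease_similarity_matrix()]).
#' @param i,j miRNA row indices or ids.
#' @return Similarity in `[0, 1]`; `NA` when either miRNA has no associated
#'   disease or a required similarity value is missing.
#' @export
mirna_functional_similarity <- function(dataset, SS, i, j) {
  if (is.character(i)) i <- match(i, dataset$mirna_ids)
  if (is.character(j)) j <- match(j, dataset$mirna_ids)
  di <- dataset$disease_ids[dataset$Y[i, ] == 1]
  dj <- dataset$disease_ids[dataset$Y[j, ] == 1]
  bma_similarity(SS, di, dj)
}

# Best-match-average over two disease id sets; NA when a set is empty or a
# best-match is unavailable (all-missing similarity row).
bma_similarity <- function(SS, di, dj) {
  if (!length(di) || !length(dj)) return(NA_real_)
  sub <- SS[di, dj, drop = FALSE]
  best_i <- apply(sub, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  best_j <- apply(sub, 2, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  (sum(best_i) + sum(best_j)) / (length(di) + length(dj))
}

#' Pairwise miRNA functional similarity matrix
#'
#' Applies [mirna_functional_similarity()] to every miRNA pair. A miRNA with
#' no associated disease gets `NA` off-diagonal (reported via a message) and
#' 1 on the diagonal.
#'
#' @inheritParams mirna_functional_similarity
#' @return A symmetric matrix with miRNA-id dimnames, class
#'   `similarity_matrix`.
#' @export
mirna_similarity_matrix <- function(dataset, SS) {
  ids <- dataset$mirna_ids
  n <- length(ids)
  dsets <- lapply(seq_len(n), function(i) dataset$disease_ids[dataset$Y[i, ] == 1])
  empty <- !lengths(dsets)
  if (any(empty)) {
    message(sum(empty), " miRNA(s) with no associated disease: ",
            "functional similarity recorded as missing")
  }
  FS <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(FS) <- 1
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        FS[i, j] <- FS[j, i] <- bma_similarity(SS, dsets[[i]], dsets[[j]])
      }
    }
  }
  structure(FS, class = c("similarity_matrix", class(FS)))
}

#' Read / write a similarity matrix as CSV
#'
#' CSV dialect: disease/miRNA ids as header row and first column; missing
#' similarity values serialized as empty cells.
#'
#' @param path CSV path.
#' @return `read_similarity_matrix`: a `similarity_matrix`;
#'   `write_similarity_matrix`: `path`, invisibly.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  dimnames(m) <- list(rownames(df), colnames(df))
  structure(m, class = c("similarity_matrix", class(m)))
}

#' @param m a similarity matrix with id dimnames.
#' @rdname read_similarity_matrix
#' @export
write_similarity_matrix <- function(m, path) {
  df <- as.data.frame(unclass(m))
  utils::write.csv(df, path, row.names = TRUE, na = "")
  invisible(path)
}
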