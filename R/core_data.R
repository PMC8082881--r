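#' Construct an association dataset
#'
#' Bundles a binary miRNA x disease adjacency matrix `Y` with its row and
#' column identifiers. Rows are always miRNAs and columns diseases; `Y[i, j]
#' == 1` records a known (experimentally supported) association, `0` an
#' unobserved pair -- not a confirmed non-association.
#'
#' @param Y numeric matrix of 0/1 entries, `n_mirna` x `n_disease`.
#' @param mirna_ids character vector of unique row identifiers.
#' @param disease_ids character vector of unique column identifiers.
#' @return An object of class `association_dataset`: a list with elements
#'   `Y` (binary matrix with dimnames), `mirna_ids`, `disease_ids`.
#' @seealso [load_association_edges()], [association_density()],
#'   [sample_negatives()]
#' @export
association_dataset <- function(Y, mirna_ids = rownames(Y),
                                disease_ids = colnames(Y)) {
  Y <- as.matrix(Y)
  if (is.null(mirna_ids) || is.null(disease_ids)) {
    stop("mirna_ids and disease_ids are required (or set as dimnames of Y)")
  }
  mirna_ids <- as.character(mirna_ids)
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(mirna_ids)) stop("duplicate miRNA identifiers")
  if (anyDuplicated(disease_ids)) stop("duplicate disease identifiers")
  if (nrow(Y) != length(mirna_ids) || ncol(Y) != length(disease_ids)) {
    stop("matrix shape does not match identifier lists")
  }
  if (anyNA(Y) || !all(Y %in% c(0, 1))) {
    stop("Y entries must be exactly 0 or 1 with no missing values")
  }
  storage.mode(Y) <- "double"
  dimnames(Y) <- list(mirna_ids, disease_ids)
  structure(list(Y = Y, mirna_ids = mirna_ids, disease_ids = disease_ids),
            class = "association_dataset")
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf("association_dataset: %d miRNAs x %d diseases, %d edges (density %.4f)\n",
              length(x$mirna_ids), length(x$disease_ids), sum(x$Y),
              association_density(x)))
  invisible(x)
}

#' Edge density of an association dataset
#'
#' @param dataset an `association_dataset`.
#' @return `sum(Y) / (n_mirna * n_disease)`.
#' @export
association_density <- function(dataset) {
  sum(dataset$Y) / (nrow(dataset$Y) * ncol(dataset$Y))
}

#' Load miRNA-disease associations from an edge list
#'
#' Reads a delimited file with columns `mirna_id`, `disease_id` and an
#' optional binary `label` column (header required; tab or comma separated,
#' decided by the first line). Rows with `label == 1` (or all rows when no
#' label column is present) become 1-entries of the adjacency matrix.
#'
#' @param path path to the edge-list file.
#' @param mirna_universe,disease_universe optional identifier vectors fixing
#'   the row/column order. Default: sorted distinct ids observed in the file.
#' @return An [association_dataset()].
#' @export
load_association_edges <- function(path, mirna_universe = NULL,
                                   disease_universe = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          check.names = FALSE)
  if (ncol(df) < 2) stop("edge list needs >= 2 columns (mirna_id, disease_id)")
  mid <- df[[1]]; did <- df[[2]]
  lab <- if (ncol(df) >= 3) as.integer(df[[3]]) else rep(1L, nrow(df))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (any(!nzchar(mid)) || any(!nzchar(did))) stop("empty identifier in edge list")
  key <- paste(mid, did, sep = "\r")
  conflict <- tapply(lab, key, function(l) length(unique(l)) > 1)
  if (any(conflict)) {
    bad <- strsplit(names(conflict)[which(conflict)[1]], "\r")[[1]]
    stop(sprintf("conflicting labels for pair (%s, %s)", bad[1], bad[2]))
  }
  keep <- !duplicated(key)
  mid <- mid[keep]; did <- did[keep]; lab <- lab[keep]
  if (is.null(mirna_universe)) mirna_universe <- sort(unique(mid))
  if (is.null(disease_universe)) disease_universe <- sort(unique(did))
  if (length(bad <- setdiff(mid, mirna_universe))) {
    stop("miRNA id outside supplied universe: ", bad[1])
  }
  if (length(bad <- setdiff(did, disease_universe))) {
    stop("disease id outside supplied universe: ", bad[1])
  }
  Y <- matrix(0, length(mirna_universe), length(disease_universe),
              dimnames = list(mirna_universe, disease_universe))
  pos <- lab == 1L
  Y[cbind(match(mid[pos], mirna_universe), match(did[pos], disease_universe))] <- 1
  association_dataset(Y, mirna_universe, disease_universe)
}

#' Write an association dataset as an edge list
#'
#' Writes the 1-entries of `Y` as a TSV with columns `mirna_id`,
#' `disease_id`, the dialect [load_association_edges()] reads back.
#'
#' @param dataset an `association_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_edges <- function(dataset, path) {
  idx <- which(dataset$Y == 1, arr.ind = TRUE)
  df <- data.frame(mirna_id = dataset$mirna_ids[idx[, 1]],
                   disease_id = dataset$disease_ids[idx[, 2]])
  df <- df[order(df$mirna_id, df$disease_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a labeled pair set by uniform negative sampling
#'
#' Returns every known positive pair (`Y == 1`) plus `n_negatives` zero
#' cells drawn uniformly at random without replacement. Unobserved pairs are
#' treated as (putative) negatives, the standard pragmatic choice when no
#' verified non-associations exist.
#'
#' @param dataset an `association_dataset`.
#' @param n_negatives number of negatives to draw; defaults to the number of
#'   positives (a balanced set).
#' @param seed integer seed; the only source of randomness (global RNG state
#'   is left untouched).
#' @return A data frame of class `pair_set` with columns `mirna_index`,
#'   `disease_index`, `mirna_id`, `disease_id`, `label`, `provenance`
#'   (`known_positive` or `sampled_negative`).
#' @export
sample_negatives <- function(dataset, n_negatives = NULL, seed = 1L) {
  Y <- dataset$Y
  pos <- which(Y == 1)
  zero <- which(Y == 0)
  if (is.null(n_negatives)) n_negatives <- length(pos)
  if (n_negatives > length(zero)) {
    stop(sprintf("n_negatives (%d) exceeds number of zero cells (%d)",
                 n_negatives, length(zero)))
  }
  neg <- withr::with_seed(seed, sample(zero, n_negatives, replace = FALSE))
  cells <- c(pos, neg)
  ij <- arrayInd(cells, dim(Y))
  out <- data.frame(
    mirna_index = ij[, 1],
    disease_index = ij[, 2],
    mirna_id = dataset$mirna_ids[ij[, 1]],
    disease_id = dataset$disease_ids[ij[, 2]],
    label = rep(c(1L, 0L), c(length(pos), length(neg))),
    provenance = rep(c("known_positive", "sampled_negative"),
                     c(length(pos), length(neg))),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pair_set", "data.frame")
  out
}
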