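#' Fuse latent and similarity features for one miRNA-disease pair
#'
#' Concatenates, in fixed block order, the miRNA's latent code, its full
#' functional-similarity profile (its row of `FS`, self-similarity
#' included), the disease's latent code, and the disease's full semantic
#' similarity profile (its row of `SS`). With latent width `k`, `n_m`
#' miRNAs and `n_d` diseases the fused vector has width
#' `k + n_m + k + n_d`. Missing similarity entries stay `NA`; they are
#' never silently imputed.
#'
#' @param m_index,d_index miRNA / disease indices into the dataset's id
#'   orders.
#' @param latent_m,latent_d latent feature matrices (entities x latent_dim)
#'   whose row order matches the dataset's miRNA / disease id order.
#' @param FS,SS miRNA functional and disease semantic similarity matrices
#'   in the same id orders.
#' @return Named numeric feature vector.
#' @export
build_pair_vector <- function(m_index, d_index, latent_m, FS, latent_d, SS) {
  check_feature_alignment(latent_m, FS, latent_d, SS)
  c(latent_m[m_index, ], FS[m_index, ], latent_d[d_index, ], SS[d_index, ])
}

check_feature_alignment <- function(latent_m, FS, latent_d, SS) {
  if (nrow(latent_m) != nrow(FS)) {
    stop(sprintf("miRNA latent rows (%d) do not match FS rows (%d)",
                 nrow(latent_m), nrow(FS)))
  }
  if (nrow(latent_d) != nrow(SS)) {
    stop(sprintf("disease latent rows (%d) do not match SS rows (%d)",
                 nrow(latent_d), nrow(SS)))
  }
  ids_m <- rownames(latent_m); ids_fs <- rownames(FS)
  if (!is.null(ids_m) && !is.null(ids_fs) && !identical(ids_m, ids_fs)) {
    bad <- which(ids_m != ids_fs)[1]
    stop(sprintf("miRNA id order mismatch at position %d: '%s' vs '%s'",
                 bad, ids_m[bad], ids_fs[bad]))
  }
  ids_d <- rownames(latent_d); ids_ss <- rownames(SS)
  if (!is.null(ids_d) && !is.null(ids_ss) && !identical(ids_d, ids_ss)) {
    bad <- which(ids_d != ids_ss)[1]
    stop(sprintf("disease id order mismatch at position %d: '%s' vs '%s'",
                 bad, ids_d[bad], ids_ss[bad]))
  }
  invisible(TRUE)
}

#' Build the per-pair feature table
#'
#' One row per labeled pair, in pair order. `mode` selects the feature
#' blocks: `"combined"` concatenates all four
#' (`[latent_m | FS row | latent_d | SS row]`), `"similarity_only"` keeps
#' the two similarity profiles, `"latent_only"` the two latent codes.
#' Block offsets are recorded in the result so any row can be sliced back
#' into its source vectors.
#'
#' @param pairs a `pair_set` (see [sample_negatives()]).
#' @inheritParams build_pair_vector
#' @param mode one of `"combined"`, `"similarity_only"`, `"latent_only"`.
#' @return Object of class `pair_feature_table`: list with `X` (feature
#'   matrix), `label`, `pairs`, `mode`, `blocks` (named list of column
#'   index ranges), `latent_dim`.
#' @export
build_feature_table <- function(pairs, latent_m, FS, latent_d, SS,
                                mode = c("combined", "similarity_only",
                                         "latent_only")) {
  mode <- match.arg(mode)
  check_feature_alignment(latent_m, FS, latent_d, SS)
  mi <- pairs$mirna_index
  di <- pairs$disease_index
  parts <- switch(mode,
    combined = list(mirna_latent = latent_m[mi, , drop = FALSE],
                    mirna_similarity = unclass(FS)[mi, , drop = FALSE],
                    disease_latent = latent_d[di, , drop = FALSE],
                    disease_similarity = unclass(SS)[di, , drop = FALSE]),
    similarity_only = list(mirna_similarity = unclass(FS)[mi, , drop = FALSE],
                           disease_similarity = unclass(SS)[di, , drop = FALSE]),
    latent_only = list(mirna_latent = latent_m[mi, , drop = FALSE],
                       disease_latent = latent_d[di, , drop = FALSE]))
  widths <- vapply(parts, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  blocks <- Map(function(s, e) s:e, starts, ends)
  X <- do.call(cbind, parts)
  colnames(X) <- unlist(Map(function(nm, w) paste0(nm, "_", seq_len(w)),
                            names(parts), widths))
  rownames(X) <- NULL
  structure(list(X = X, label = pairs$label, pairs = pairs, mode = mode,
                 blocks = blocks,
                 latent_dim = ncol(latent_m)),
            class = "pair_feature_table")
}

#' @export
print.pair_feature_table <- function(x, ...) {
  cat(sprintf("pair_feature_table: %d pairs x %d features (%s; blocks: %s)\n",
              nrow(x$X), ncol(x$X), x$mode,
              paste(names(x$blocks), collapse = ", ")))
  invisible(x)
}

#' Export a feature table to CSV with a JSON sidecar
#'
#' The sidecar records the block offsets, latent width, mode and pair ids
#' needed to reinterpret the columns.
#'
#' @param table a `pair_feature_table`.
#' @param path CSV output path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(mirna_id = table$pairs$mirna_id,
                   disease_id = table$pairs$disease_id,
                   label = table$label, table$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(mode = table$mode, latent_dim = table$latent_dim,
               blocks = lapply(table$blocks, range))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
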