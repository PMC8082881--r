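#' Classification metrics for scored pairs
#'
#' AUC is computed by the rank statistic (the probability that a random
#' positive outscores a random negative, ties counted 1/2 -- identical to
#' trapezoidal ROC integration). AUPR integrates the precision-recall
#' curve stepwise over distinct score thresholds. Thresholded metrics come
#' from the confusion counts at `threshold` (a score at or above the
#' threshold predicts the positive class).
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector of the same length.
#' @param threshold decision threshold for the confusion-based metrics
#'   (default 0.5).
#' @return Object of class `metrics_report`: list with `auc`, `aupr`,
#'   `precision`, `recall`, `f1`, `accuracy`, `threshold` and `counts`
#'   (named TP, FP, TN, FN).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  tp_cum <- cumsum(labels[ord] == 1)
  fp_cum <- cumsum(labels[ord] == 0)
  # collapse tied scores: evaluate at the last index of each distinct score
  keep <- which(!duplicated(scores[ord], fromLast = TRUE))
  tp_k <- tp_cum[keep]; fp_k <- fp_cum[keep]
  prec <- tp_k / (tp_k + fp_k)
  rec <- tp_k / n_pos
  aupr <- sum(diff(c(0, rec)) * prec)

  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1)
  FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  precision <- if (TP + FP > 0) TP / (TP + FP) else NaN
  recall <- TP / (TP + FN)
  f1 <- if (is.finite(precision) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NaN
  structure(list(auc = auc, aupr = aupr, precision = precision,
                 recall = recall, f1 = f1,
                 accuracy = (TP + TN) / length(labels),
                 threshold = threshold,
                 counts = c(TP = TP, FP = FP, TN = TN, FN = FN)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUC %.4f | AUPR %.4f | acc %.4f | P %.4f R %.4f F1 %.4f (thr %.2f)\n",
              x$auc, x$aupr, x$accuracy, x$precision, x$recall, x$f1,
              x$threshold))
  invisible(x)
}

#' Random k-fold assignment over labeled pairs
#'
#' @param pairs a `pair_set` (or anything with rows).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1:k`, one per pair; fold sizes
#'   differ by at most one.
#' @export
kfold_split <- function(pairs, k = 5L, seed = 1L) {
  n <- NROW(pairs)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("fewer pairs than folds")
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# Features derived from one (possibly masked) association matrix: miRNA
# functional similarity and, when needed, the two latent towers. The two
# autoencoders use consecutive seeds derived from the config seed.
pipeline_features <- function(dataset, SS, config = ae_config(),
                              need_latent = TRUE) {
  FS <- suppressMessages(mirna_similarity_matrix(dataset, SS))
  n_m <- length(dataset$mirna_ids)
  n_d <- length(dataset$disease_ids)
  if (need_latent) {
    orig <- split_original_features(dataset)
    cfg_m <- config
    cfg_d <- config
    cfg_d$seed <- config$seed + 1L
    latent_m <- encode(train_stacked_autoencoder(orig$M, cfg_m), orig$M)
    latent_d <- encode(train_stacked_autoencoder(orig$D, cfg_d), orig$D)
  } else {
    latent_m <- matrix(0, n_m, 1, dimnames = list(dataset$mirna_ids, NULL))
    latent_d <- matrix(0, n_d, 1, dimnames = list(dataset$disease_ids, NULL))
  }
  list(FS = FS, latent_m = latent_m, latent_d = latent_d)
}

# Zero the test-fold positive cells of Y (leakage masking).
mask_test_positives <- function(dataset, pairs, test_idx) {
  Y <- dataset$Y
  tp <- pairs[test_idx, , drop = FALSE]
  tp <- tp[tp$label == 1, , drop = FALSE]
  if (nrow(tp)) Y[cbind(tp$mirna_index, tp$disease_index)] <- 0
  association_dataset(Y, dataset$mirna_ids, dataset$disease_ids)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Splits the labeled pairs into `k` random folds; for each fold the
#' classifier is trained on the remaining folds and evaluated on the held
#' fold. Feature construction honours `leakage_mode`:
#' `"masked"` (default) zeroes the test fold's positive cells in `Y` before
#' the autoencoders and the miRNA functional similarity are computed, so no
#' test positive can leak into any training artifact; `"paper"` computes
#' latent features and similarities once from the full matrix, matching
#' pipelines that learn features globally before splitting. The disease
#' semantic similarity depends only on the DAG and is computed once either
#' way. The classifier itself is always trained on training folds only.
#'
#' @param dataset an [association_dataset()].
#' @param dag a [disease_dag()] over the dataset's diseases.
#' @param pairs optional `pair_set`; defaults to all positives plus an equal
#'   number of uniformly sampled negatives.
#' @param mode feature mode passed to [build_feature_table()].
#' @param k number of folds (default 5).
#' @param seed integer seed driving negative sampling and fold assignment.
#' @param leakage_mode `"masked"` or `"paper"`.
#' @param delta semantic-similarity decay factor.
#' @param ae_cfg an [ae_config()].
#' @param clf_cfg a [classifier_config()].
#' @param n_negatives negatives to sample when `pairs` is `NULL`.
#' @return Object of class `cv_result`: list with `folds` (per-fold
#'   `metrics_report`s), `mean` and `sd` (named metric vectors),
#'   `fold_assignment`, `pairs`, and the configs used.
#' @export
cross_validate <- function(dataset, dag, pairs = NULL,
                           mode = c("combined", "similarity_only",
                                    "latent_only"),
                           k = 5L, seed = 1L,
                           leakage_mode = c("masked", "paper"),
                           delta = 0.5,
                           ae_cfg = ae_config(),
                           clf_cfg = classifier_config(),
                           n_negatives = NULL) {
  mode <- match.arg(mode)
  leakage_mode <- match.arg(leakage_mode)
  if (is.null(pairs)) {
    pairs <- sample_negatives(dataset, n_negatives, seed = seed)
  }
  folds <- kfold_split(pairs, k = k, seed = seed + 1L)
  SS <- disease_similarity_matrix(dag, dataset$disease_ids, delta = delta)
  need_latent <- mode != "similarity_only"
  global_feats <- if (leakage_mode == "paper") {
    pipeline_features(dataset, SS, ae_cfg, need_latent)
  }
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    feats <- if (leakage_mode == "masked") {
      pipeline_features(mask_test_positives(dataset, pairs, test_idx),
                        SS, ae_cfg, need_latent)
    } else {
      global_feats
    }
    train_tab <- build_feature_table(pairs[-test_idx, , drop = FALSE],
                                     feats$latent_m, feats$FS,
                                     feats$latent_d, SS, mode = mode)
    test_tab <- build_feature_table(pairs[test_idx, , drop = FALSE],
                                    feats$latent_m, feats$FS,
                                    feats$latent_d, SS, mode = mode)
    model <- suppressWarnings(train_classifier(train_tab, clf_cfg))
    scores <- predict_scores(model, test_tab)
    reports[[f]] <- compute_metrics(test_tab$label, scores)
  }
  metric_names <- c("auc", "aupr", "precision", "recall", "f1", "accuracy")
  per_fold <- sapply(metric_names,
                     function(mn) vapply(reports, `[[`, numeric(1), mn))
  structure(list(folds = reports,
                 mean = colMeans(per_fold),
                 sd = apply(per_fold, 2, stats::sd),
                 fold_assignment = folds, pairs = pairs, mode = mode,
                 leakage_mode = leakage_mode, k = k, seed = seed,
                 ae_cfg = ae_cfg, clf_cfg = clf_cfg),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold, mode %s, leakage %s\n", x$k, x$mode,
              x$leakage_mode))
  cat(sprintf("  mean AUC %.4f (sd %.4f) | AUPR %.4f | accuracy %.4f\n",
              x$mean["auc"], x$sd["auc"], x$mean["aupr"],
              x$mean["accuracy"]))
  invisible(x)
}

#' Rank candidate miRNAs for one disease
#'
#' Leave-one-disease-out case study: every miRNA already associated with
#' the disease is removed from the candidate set and its association cells
#' are zeroed in `Y`; features are rebuilt from the redacted matrix, the
#' classifier is trained on the redacted positives plus sampled negatives,
#' and the remaining miRNAs are scored against the disease and sorted by
#' decreasing score.
#'
#' @inheritParams cross_validate
#' @param disease_id the disease to screen.
#' @param top_n how many top candidates to surface (default 10).
#' @return Object of class `ranked_candidates`: list with `disease_id`,
#'   `candidates` (data frame `rank`, `mirna_id`, `score`, all candidates,
#'   scores non-increasing), `top` (first `top_n` rows), `excluded`
#'   (the removed miRNA ids), `n_candidates`.
#' @export
rank_candidates_for_disease <- function(dataset, dag, disease_id,
                                        mode = "combined",
                                        delta = 0.5,
                                        ae_cfg = ae_config(),
                                        clf_cfg = classifier_config(),
                                        top_n = 10L, seed = 1L,
                                        n_negatives = NULL) {
  j <- match(disease_id, dataset$disease_ids)
  if (is.na(j)) stop("disease not in dataset: ", disease_id)
  excluded <- dataset$mirna_ids[dataset$Y[, j] == 1]
  candidates <- setdiff(dataset$mirna_ids, excluded)
  if (!length(candidates)) {
    stop("every miRNA is already associated with ", disease_id)
  }
  Y0 <- dataset$Y
  Y0[, j] <- 0
  redacted <- association_dataset(Y0, dataset$mirna_ids, dataset$disease_ids)
  SS <- disease_similarity_matrix(dag, dataset$disease_ids, delta = delta)
  feats <- pipeline_features(redacted, SS, ae_cfg,
                             need_latent = mode != "similarity_only")
  pairs <- sample_negatives(redacted, n_negatives, seed = seed)
  train_tab <- build_feature_table(pairs, feats$latent_m, feats$FS,
                                   feats$latent_d, SS, mode = mode)
  model <- suppressWarnings(train_classifier(train_tab, clf_cfg))
  cand_pairs <- data.frame(
    mirna_index = match(candidates, dataset$mirna_ids),
    disease_index = j,
    mirna_id = candidates, disease_id = disease_id,
    label = 0L, provenance = "candidate", stringsAsFactors = FALSE)
  cand_tab <- build_feature_table(cand_pairs, feats$latent_m, feats$FS,
                                  feats$latent_d, SS, mode = mode)
  scores <- predict_scores(model, cand_tab)
  ord <- order(scores, decreasing = TRUE)
  ranked <- data.frame(rank = seq_along(ord),
                       mirna_id = candidates[ord],
                       score = scores[ord], stringsAsFactors = FALSE)
  structure(list(disease_id = disease_id, candidates = ranked,
                 top = utils::head(ranked, top_n), excluded = excluded,
                 n_candidates = nrow(ranked)),
            class = "ranked_candidates")
}

#' @export
print.ranked_candidates <- function(x, ...) {
  cat(sprintf("ranked_candidates for '%s': %d candidates (%d excluded)\n",
              x$disease_id, x$n_candidates, length(x$excluded)))
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Write ranked candidates as TSV
#'
#' Columns `rank`, `mirna_id`, `score`, all candidates in rank order.
#'
#' @param ranked a `ranked_candidates`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_candidates <- function(ranked, path) {
  utils::write.table(ranked$candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
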