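test_that("metrics match hand-computed values on small cases", {
  m <- compute_metrics(c(1, 0), c(0.9, 0.1))
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)

  m <- compute_metrics(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2))
  expect_equal(m$auc, 0.75)
  expect_equal(unname(m$counts), c(1, 1, 1, 1))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  fpr <- m$counts[["FP"]] / (m$counts[["TN"]] + m$counts[["FP"]])
  expect_equal(fpr, 0.5)

  expect_error(compute_metrics(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC equals the exhaustive pairwise-comparison oracle", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- sample(10:200, 1)
      labels <- rbinom(n, 1, 0.4)
      if (all(labels == labels[1])) labels[1] <- 1 - labels[1]
      # quantized scores force ties
      scores <- round(runif(n), sample(1:2, 1))
    })
    expect_equal(compute_metrics(labels, scores)$auc,
                 pairwise_auc(labels, scores), tolerance = 1e-12)
  }
})

test_that("AUC and AUPR agree with an independent ROC library", {
  skip_if_not_installed("pROC")
  withr::with_seed(3, {
    labels <- rbinom(120, 1, 0.5)
    scores <- runif(120) + labels * 0.4
  })
  ours <- compute_metrics(labels, scores)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
  expect_equal(ours$auc, ref, tolerance = 1e-12)
})

test_that("confusion-derived quantities are internally consistent", {
  withr::with_seed(11, {
    labels <- rbinom(300, 1, 0.45)
    scores <- runif(300)
  })
  m <- compute_metrics(labels, scores, threshold = 0.4)
  cts <- m$counts
  expect_equal(sum(cts), 300)
  expect_equal(m$accuracy, (cts[["TP"]] + cts[["TN"]]) / 300)
  expect_equal(m$recall, cts[["TP"]] / (cts[["TP"]] + cts[["FN"]]))
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
})

test_that("k-fold assignment partitions pairs into near-equal folds", {
  pairs <- data.frame(x = 1:10)
  f <- kfold_split(pairs, k = 5, seed = 2)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_identical(f, kfold_split(pairs, k = 5, seed = 2))
  expect_false(identical(f, kfold_split(pairs, k = 5, seed = 3)))
  expect_error(kfold_split(pairs, k = 1, seed = 1), "at least 2")
  f2 <- kfold_split(data.frame(x = 1:13), k = 5, seed = 4)
  expect_true(max(table(f2)) - min(table(f2)) <= 1)
  expect_setequal(unique(f2), 1:5)
})

test_that("masked-mode features are blind to test-fold positives", {
  synth <- small_synth(seed = 9)
  ds <- synth$dataset
  SS <- disease_similarity_matrix(synth$dag, ds$disease_ids)
  pairs <- sample_negatives(ds, seed = 9)
  folds <- kfold_split(pairs, k = 5, seed = 10)
  test_idx <- which(folds == 1)
  # canary: turn one test-fold negative into a test-fold positive
  canary <- test_idx[which(pairs$label[test_idx] == 0)[1]]
  Y2 <- ds$Y
  Y2[pairs$mirna_index[canary], pairs$disease_index[canary]] <- 1
  ds2 <- association_dataset(Y2, ds$mirna_ids, ds$disease_ids)
  pairs2 <- pairs
  pairs2$label[canary] <- 1L
  cfg <- tiny_ae_cfg(seed = 9)
  f1 <- mdlatent:::pipeline_features(
    mdlatent:::mask_test_positives(ds, pairs, test_idx), SS, cfg)
  f2 <- mdlatent:::pipeline_features(
    mdlatent:::mask_test_positives(ds2, pairs2, test_idx), SS, cfg)
  expect_identical(f1$latent_m, f2$latent_m)
  expect_identical(f1$latent_d, f2$latent_d)
  expect_identical(unclass(f1$FS), unclass(f2$FS))
})

test_that("cross-validation runs five folds by default and is reproducible", {
  synth <- small_synth(seed = 12)
  run <- function() cross_validate(synth$dataset, synth$dag,
                                   seed = 12, leakage_mode = "masked",
                                   ae_cfg = tiny_ae_cfg(seed = 12),
                                   clf_cfg = tiny_clf_cfg(seed = 12))
  cv1 <- run()
  expect_equal(cv1$k, 5L)
  expect_length(cv1$folds, 5)
  expect_setequal(unique(cv1$fold_assignment), 1:5)
  expect_true(all(is.finite(cv1$mean)))
  cv2 <- run()
  expect_identical(cv1$mean, cv2$mean)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
})

test_that("paper-mode leakage computes features once from the full matrix", {
  synth <- small_synth(seed = 13)
  cv <- cross_validate(synth$dataset, synth$dag, seed = 13,
                       leakage_mode = "paper",
                       ae_cfg = tiny_ae_cfg(seed = 13),
                       clf_cfg = tiny_clf_cfg(seed = 13))
  expect_equal(cv$leakage_mode, "paper")
  expect_true(all(sapply(cv$folds, function(f) f$auc) > 0))
})

test_that("candidate ranking excludes known miRNAs and sorts by score", {
  synth <- small_synth(seed = 14)
  ds <- synth$dataset
  d <- ds$disease_ids[which.max(colSums(ds$Y))]
  n_known <- sum(ds$Y[, d])
  r <- rank_candidates_for_disease(ds, synth$dag, d,
                                   ae_cfg = tiny_ae_cfg(seed = 14),
                                   clf_cfg = tiny_clf_cfg(seed = 14),
                                   top_n = 5, seed = 14)
  expect_equal(r$n_candidates, length(ds$mirna_ids) - n_known)
  expect_length(intersect(r$candidates$mirna_id, r$excluded), 0)
  expect_true(all(diff(r$candidates$score) <= 0))
  expect_equal(nrow(r$top), 5)

  # a disease with no known associations keeps every miRNA as candidate
  Y0 <- ds$Y
  Y0[, 1] <- 0
  ds0 <- association_dataset(Y0, ds$mirna_ids, ds$disease_ids)
  r0 <- rank_candidates_for_disease(ds0, synth$dag, ds$disease_ids[1],
                                    ae_cfg = tiny_ae_cfg(seed = 1),
                                    clf_cfg = tiny_clf_cfg(seed = 1), seed = 1)
  expect_equal(r0$n_candidates, length(ds$mirna_ids))

  # all miRNAs associated -> nothing to rank
  Y1 <- ds$Y
  Y1[, 2] <- 1
  ds1 <- association_dataset(Y1, ds$mirna_ids, ds$disease_ids)
  expect_error(rank_candidates_for_disease(ds1, synth$dag, ds$disease_ids[2],
                                           seed = 1),
               "already associated")
})
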