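# Shared fixtures: toy DAGs, tiny datasets, scaled-down training configs.

chain_dag <- function() {
  # R -> C -> D
  disease_dag(data.frame(parent = c("R", "C"), child = c("C", "D")))
}

diamond_dag <- function() {
  # R -> A -> D, R -> B -> D
  disease_dag(data.frame(parent = c("R", "R", "A", "B"),
                         child = c("A", "B", "D", "D")))
}

sibling_dag <- function() {
  # A, B children of shared root R
  disease_dag(data.frame(parent = c("R", "R"), child = c("A", "B")))
}

tiny_dataset <- function() {
  Y <- matrix(c(1, 1, 0,
                1, 0, 0,
                0, 0, 1,
                0, 1, 1), nrow = 4, byrow = TRUE)
  association_dataset(Y, paste0("m", 1:4), c("A", "B", "C"))
}

# configs scaled for test-size inputs
tiny_ae_cfg <- function(seed = 1L, latent = 4L, hidden = 8L,
                        pre = 5L, fine = 10L) {
  ae_config(latent_dim = latent, hidden_dims = c(hidden, latent),
            epochs_pretrain = pre, epochs_finetune = fine, seed = seed)
}

tiny_clf_cfg <- function(seed = 1L, nrounds = 30L) {
  classifier_config("gbdt", nrounds = nrounds, seed = seed)
}

# small planted dataset for fast pipeline tests
small_synth <- function(seed = 1L) {
  generate_synthetic_dataset(synthetic_config(
    n_mirna = 40L, n_disease = 25L, k = 2L, target_density = 0.08,
    dag_depth = 3L, dag_branching = 3L, seed = seed))
}

# synthetic-scale training configuration used for the full-size planted
# dataset (input widths 100/150): tight bottleneck, full-batch Adam
ae_cfg_synth <- function(seed = 1L) {
  ae_config(latent_dim = 8L, hidden_dims = c(32L, 8L), learning_rate = 2e-3,
            epochs_pretrain = 100L, epochs_finetune = 200L, seed = seed)
}

# independent oracle for semantic contributions: the contribution of d to
# focus equals the maximum over all downward paths d -> ... -> focus of
# delta^(path length), found by exhaustive DFS path enumeration
path_enum_contribution <- function(dag, d, focus, delta) {
  if (d == focus) return(1)
  best <- -Inf
  walk <- function(node, len) {
    if (node == focus) {
      best <<- max(best, delta^len)
      return()
    }
    for (ch in dag$children[[node]]) walk(ch, len + 1L)
  }
  walk(d, 0L)
  if (is.finite(best)) best else NA_real_
}

# brute-force AUC: all positive-negative pairs, ties get half credit
pairwise_auc <- function(labels, scores) {
  p <- scores[labels == 1]
  n <- scores[labels == 0]
  tot <- 0
  for (a in p) tot <- tot + sum(a > n) + 0.5 * sum(a == n)
  tot / (length(p) * length(n))
}
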