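#' Synthetic dataset configuration
#'
#' Defines the planted-structure generator: miRNAs and diseases are
#' assigned to `k` latent blocks; a pair is associated with probability
#' `p_in` when the blocks match and `p_in / in_out_ratio` otherwise, the
#' two rates solved so that the expected edge density equals
#' `target_density`. Label noise is edge-proportional: each planted edge is
#' dropped with probability `noise_rate` and a matching expected number of
#' spurious edges is added uniformly over non-edges, so `noise_rate` is the
#' fraction of associations corrupted (at realistic sparsity, flipping a
#' fixed fraction of *cells* instead would swamp the planted signal with
#' spurious edges). A `heldout_fraction` of the surviving planted edges is
#' then withheld as held-out truths (zeroed in `Y`), and a random rooted
#' DAG places same-block diseases in the same subtree so that semantic
#' similarity correlates with block identity.
#'
#' @param n_mirna,n_disease entity counts (defaults 150, 100).
#' @param k number of planted blocks (default 4).
#' @param target_density expected pre-withholding edge density (default
#'   0.03, the sparsity regime typical of curated association matrices).
#' @param in_out_ratio ratio `p_in / p_out` (default 20).
#' @param dag_depth,dag_branching shape of the disease DAG (defaults 4, 3).
#' @param noise_rate label-flip probability per planted edge (default 0.01):
#'   the fraction of planted edges dropped, and of the edge count re-added
#'   as spurious edges on random non-edges.
#' @param heldout_fraction fraction of planted positives withheld (default
#'   0.1).
#' @param seed integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mirna = 150L, n_disease = 100L, k = 4L,
                             target_density = 0.03, in_out_ratio = 20,
                             dag_depth = 4L, dag_branching = 3L,
                             noise_rate = 0.01, heldout_fraction = 0.1,
                             seed = 1L) {
  if (!(target_density > 0 && target_density < 1)) {
    stop("target_density must lie in (0, 1)")
  }
  if (k > min(n_mirna, n_disease)) stop("k exceeds entity counts")
  if (noise_rate < 0 || noise_rate >= 0.5) stop("noise_rate must be in [0, 0.5)")
  structure(list(n_mirna = as.integer(n_mirna),
                 n_disease = as.integer(n_disease), k = as.integer(k),
                 target_density = target_density,
                 in_out_ratio = in_out_ratio,
                 dag_depth = as.integer(dag_depth),
                 dag_branching = as.integer(dag_branching),
                 noise_rate = noise_rate,
                 heldout_fraction = heldout_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic association dataset with planted structure
#'
#' Produces a bipartite stochastic block model realization (low-rank
#' association structure for the autoencoder to recover), a block-aligned
#' disease DAG (so DAG-based semantic similarity tracks block identity),
#' ground-truth block assignments, and a held-out true-positive list for
#' recovery experiments. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return Object of class `synthetic_dataset`: list with `dataset`
#'   (an [association_dataset()]), `dag` (a [disease_dag()]),
#'   `mirna_block`, `disease_block` (named integer vectors), `heldout`
#'   (data frame `mirna_id`, `disease_id` of withheld positives, all 0 in
#'   `Y`), and `config`.
#' @export
generate_synthetic_dataset <- function(config = synthetic_config()) {
  nm <- config$n_mirna; nd <- config$n_disease; k <- config$k
  nu <- config$noise_rate
  withr::with_seed(config$seed, {
    mirna_block <- sample(rep_len(seq_len(k), nm))
    disease_block <- sample(rep_len(seq_len(k), nd))
    same <- outer(mirna_block, disease_block, "==")
    f_same <- mean(same)
    # noise preserves the expected edge count, so solve rates directly
    p_in <- config$target_density /
      (f_same + (1 - f_same) / config$in_out_ratio)
    if (p_in > 1) stop("target_density infeasible for given k and ratio")
    p_out <- p_in / config$in_out_ratio
    P <- ifelse(same, p_in, p_out)
    planted <- matrix(stats::runif(nm * nd) < P, nm, nd)
    Y <- planted
    pos_idx <- which(planted)
    if (nu > 0 && length(pos_idx)) {
      drop <- pos_idx[stats::runif(length(pos_idx)) < nu]
      Y[drop] <- FALSE
      zeros <- which(!planted)
      n_spur <- stats::rbinom(1, length(pos_idx), nu)
      if (n_spur > 0) Y[sample(zeros, min(n_spur, length(zeros)))] <- TRUE
    }
    # withhold a fraction of the surviving planted edges as hidden truths
    surv <- which(planted & Y)
    n_hold <- floor(config$heldout_fraction * length(surv))
    hold <- if (n_hold > 0) sample(surv, n_hold) else integer(0)
    Y[hold] <- FALSE
    mirna_ids <- sprintf("mir-%03d", seq_len(nm))
    disease_ids <- sprintf("disease-%03d", seq_len(nd))
    dag <- block_aligned_dag(disease_ids, disease_block, config$dag_depth,
                             config$dag_branching)
  })
  ds <- association_dataset(Y * 1, mirna_ids, disease_ids)
  hij <- arrayInd(hold, c(nm, nd))
  heldout <- data.frame(mirna_id = mirna_ids[hij[, 1]],
                        disease_id = disease_ids[hij[, 2]],
                        stringsAsFactors = FALSE)
  names(mirna_block) <- mirna_ids
  names(disease_block) <- disease_ids
  structure(list(dataset = ds, dag = dag, mirna_block = mirna_block,
                 disease_block = disease_block, heldout = heldout,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d x %d, %d blocks, density %.4f, %d held-out positives\n",
    x$config$n_mirna, x$config$n_disease, x$config$k,
    association_density(x$dataset), nrow(x$heldout)))
  invisible(x)
}

# Rooted DAG whose first level is one subtree root per block; each disease
# term attaches to a uniformly chosen same-block node subject to the depth
# cap, preferring parents below the branching limit. Runs inside the
# caller's seeded RNG scope.
block_aligned_dag <- function(disease_ids, disease_block, depth, branching) {
  k <- max(disease_block)
  root <- "term-root"
  block_roots <- sprintf("term-block-%d", seq_len(k))
  edges <- data.frame(parent = root, child = block_roots,
                      stringsAsFactors = FALSE)
  node_depth <- c(stats::setNames(0L, root),
                  stats::setNames(rep(1L, k), block_roots))
  n_children <- integer(0)
  for (b in seq_len(k)) {
    members <- disease_ids[disease_block == b]
    placed <- block_roots[b]
    for (d in members) {
      eligible <- placed[node_depth[placed] < depth]
      if (!length(eligible)) eligible <- block_roots[b]
      counts <- n_children[eligible]
      counts[is.na(counts)] <- 0L
      open <- eligible[counts < branching]
      pool <- if (length(open)) open else eligible
      parent <- if (length(pool) == 1) pool else sample(pool, 1)
      edges <- rbind(edges, data.frame(parent = parent, child = d,
                                       stringsAsFactors = FALSE))
      node_depth[d] <- node_depth[parent] + 1L
      n_children[parent] <- if (is.na(n_children[parent])) 1L else
        n_children[parent] + 1L
      placed <- c(placed, d)
    }
  }
  disease_dag(edges)
}

#' Generate a random rooted DAG
#'
#' Grows a single-rooted tree-shaped DAG term by term: each new term
#' attaches to a uniformly chosen existing node of depth `< depth`,
#' preferring parents with fewer than `branching` children, so the
#' maximum root-to-leaf depth never exceeds `depth` and every term is
#' reachable from the root.
#'
#' @param n_terms number of terms (>= 1); terms are named `t1 ... tn` with
#'   `t1` the root.
#' @param depth maximum depth (root has depth 0).
#' @param branching preferred maximum child count per node.
#' @param seed integer seed.
#' @return A [disease_dag()].
#' @export
generate_random_dag <- function(n_terms, depth = 4L, branching = 3L,
                                seed = 1L) {
  if (n_terms < 1) stop("n_terms must be >= 1")
  terms <- paste0("t", seq_len(n_terms))
  if (n_terms == 1) return(disease_dag(NULL, terms = terms))
  withr::with_seed(seed, {
    node_depth <- stats::setNames(integer(n_terms), terms)
    n_children <- stats::setNames(integer(n_terms), terms)
    parent <- character(n_terms - 1)
    for (i in seq(2, n_terms)) {
      existing <- terms[seq_len(i - 1)]
      eligible <- existing[node_depth[existing] < depth]
      open <- eligible[n_children[eligible] < branching]
      pool <- if (length(open)) open else eligible
      p <- if (length(pool) == 1) pool else sample(pool, 1)
      parent[i - 1] <- p
      node_depth[terms[i]] <- node_depth[p] + 1L
      n_children[p] <- n_children[p] + 1L
    }
  })
  disease_dag(data.frame(parent = parent, child = terms[-1],
                         stringsAsFactors = FALSE), terms = terms)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the edge-list and DAG TSV dialects that
#' [load_association_edges()] and [read_disease_dag()] read back, plus the
#' held-out positives and block assignments.
#'
#' @param synth a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(synth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_association_edges(synth$dataset, file.path(dir, "associations.tsv"))
  write_disease_dag(synth$dag, file.path(dir, "dag.tsv"))
  utils::write.table(synth$heldout, file.path(dir, "heldout.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  blocks <- data.frame(
    id = c(names(synth$mirna_block), names(synth$disease_block)),
    kind = rep(c("mirna", "disease"),
               c(length(synth$mirna_block), length(synth$disease_block))),
    block = c(synth$mirna_block, synth$disease_block))
  utils::write.table(blocks, file.path(dir, "blocks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
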