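#' Run the full prediction pipeline from a configuration
#'
#' Loads (or simulates) an association matrix and disease DAG, computes the
#' two similarity matrices, trains the latent-feature autoencoders, runs
#' cross-validated evaluation, and optionally ranks candidates for chosen
#' diseases. Every artifact -- the resolved configuration, similarity
#' matrices, latent features, cross-validation result, rankings, and a run
#' manifest with stage timings and seeds -- is written under `out_dir`, so
#' a run can be reproduced bit-identically from its own output.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `assoc` (edge-list path) and `dag` (DAG TSV path), or `simulate = TRUE`
#'   with optional [synthetic_config()] fields under `synthetic`;
#'   optional `annotation` (TSV path), `delta`, `mode`, `leakage_mode`,
#'   `folds`, `seed`, `classifier` (kind), `latent_dim`, `hidden`,
#'   `epochs_pretrain`, `epochs_finetune`, `lambda`, `nrounds`, `top_n`,
#'   `rank_diseases` (character vector).
#' @param out_dir output directory (created if missing).
#' @return The output directory path, invisibly; the cross-validation
#'   result is written to `cv_result.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    requireNamespace("yaml", quietly = TRUE) ||
      stop("yaml package required to read config files")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(simulate = FALSE, delta = 0.5, mode = "combined",
                   leakage_mode = "masked", folds = 5L, seed = 1L,
                   classifier = "gbdt", latent_dim = 64L, hidden = NULL,
                   epochs_pretrain = 100L, epochs_finetune = 200L,
                   lambda = 1e-4, nrounds = NULL, top_n = 10L,
                   rank_diseases = character(0))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tic <- function() Sys.time()
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(as.numeric(difftime(tic(), t0, units = "secs")), 3)
    out
  }

  if (isTRUE(cfg$simulate)) {
    synth <- stage("simulate", {
      sc <- do.call(synthetic_config,
                    utils::modifyList(list(seed = cfg$seed),
                                      cfg$synthetic %||% list()))
      generate_synthetic_dataset(sc)
    })
    dataset <- synth$dataset
    dag <- synth$dag
    write_synthetic_dataset(synth, file.path(out_dir, "simulated"))
  } else {
    dataset <- stage("load_associations", {
      if (is.null(cfg$assoc)) stop("no 'assoc' path in config")
      load_association_edges(cfg$assoc)
    })
    dag <- stage("load_dag", read_disease_dag(cfg$dag, cfg$annotation))
  }

  hidden <- cfg$hidden %||% c(max(2L * cfg$latent_dim, 8L), cfg$latent_dim)
  ae_cfg <- ae_config(latent_dim = cfg$latent_dim, hidden_dims = hidden,
                      lambda = cfg$lambda,
                      epochs_pretrain = cfg$epochs_pretrain,
                      epochs_finetune = cfg$epochs_finetune,
                      seed = cfg$seed)
  clf_args <- list(kind = cfg$classifier, seed = cfg$seed)
  if (!is.null(cfg$nrounds) && cfg$classifier == "gbdt") {
    clf_args$nrounds <- cfg$nrounds
  }
  clf_cfg <- do.call(classifier_config, clf_args)

  SS <- stage("disease_similarity",
              disease_similarity_matrix(dag, dataset$disease_ids,
                                        delta = cfg$delta))
  write_similarity_matrix(SS, file.path(out_dir, "disease_similarity.csv"))
  feats <- stage("features", pipeline_features(dataset, SS, ae_cfg))
  write_similarity_matrix(feats$FS, file.path(out_dir, "mirna_similarity.csv"))
  utils::write.csv(data.frame(id = rownames(feats$latent_m), feats$latent_m),
                   file.path(out_dir, "latent_mirna.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(feats$latent_d), feats$latent_d),
                   file.path(out_dir, "latent_disease.csv"), row.names = FALSE)

  cv <- stage("cross_validate",
              cross_validate(dataset, dag, mode = cfg$mode, k = cfg$folds,
                             seed = cfg$seed, leakage_mode = cfg$leakage_mode,
                             delta = cfg$delta, ae_cfg = ae_cfg,
                             clf_cfg = clf_cfg))
  cv_json <- list(
    k = cv$k, mode = cv$mode, leakage_mode = cv$leakage_mode,
    mean = as.list(cv$mean), sd = as.list(cv$sd),
    folds = lapply(cv$folds, function(f) {
      list(auc = f$auc, aupr = f$aupr, precision = f$precision,
           recall = f$recall, f1 = f$f1, accuracy = f$accuracy,
           counts = as.list(f$counts))
    }))
  jsonlite::write_json(cv_json, file.path(out_dir, "cv_result.json"),
                       auto_unbox = TRUE, digits = NA)

  for (d in cfg$rank_diseases) {
    r <- stage(paste0("rank_", d),
               rank_candidates_for_disease(dataset, dag, d, mode = cfg$mode,
                                           delta = cfg$delta, ae_cfg = ae_cfg,
                                           clf_cfg = clf_cfg,
                                           top_n = cfg$top_n,
                                           seed = cfg$seed))
    write_ranked_candidates(r, file.path(out_dir,
                                         paste0("ranking_", gsub("[^A-Za-z0-9._-]", "_", d), ".tsv")))
  }

  manifest <- list(config = cfg, timings = timings,
                   n_mirna = length(dataset$mirna_ids),
                   n_disease = length(dataset$disease_ids),
                   density = association_density(dataset),
                   package_version = as.character(utils::packageVersion("mdlatent")),
                   backend_versions = list(
                     xgboost = as.character(utils::packageVersion("xgboost"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
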