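#' @title End-to-end pipeline orchestration
#' @description Runs the stages (simulate, build-features, train, evaluate,
#'   permute, explain) against a dataset directory, writing deterministic
#'   artifacts and a JSON run manifest. A single global seed fans out to
#'   fixed per-stage offsets so each stage is independently reproducible.
#' @name pipeline_cli
NULL

.STAGE_SEEDS <- c(simulate = 101L, folds = 202L, train = 303L,
                  permute = 404L)

.stage_seed <- function(seed, stage) as.integer(seed) + .STAGE_SEEDS[[stage]]

#' Run pipeline stages
#'
#' @param config a config list ([default_config()]) or path to a YAML
#'   config. Recognized extra keys: `preset`, `n_genes`, `n_tfs`,
#'   `n_samples` for the simulate stage.
#' @param out_dir output directory; the dataset lives in
#'   `out_dir/data`, artifacts in `out_dir/artifacts`.
#' @param stage one of `"simulate"`, `"build-features"`, `"train"`,
#'   `"evaluate"`, `"permute"`, `"explain"`, `"all"`.
#' @return invisibly, a list of the stage results produced in this call.
#' @export
run_pipeline <- function(config, out_dir,
                         stage = c("all", "simulate", "build-features",
                                   "train", "evaluate", "permute",
                                   "explain")) {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) read_config(config) else config
  data_dir <- file.path(out_dir, "data")
  art_dir <- file.path(out_dir, "artifacts")
  dir.create(art_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "build-features", "train", "evaluate", "permute",
      "explain")
  } else stage
  res <- list()
  t0 <- Sys.time()
  timings <- list()
  for (st in stages) {
    t1 <- Sys.time()
    res <- switch(st,
      "simulate" = .stage_simulate(cfg, data_dir, res),
      "build-features" = .stage_features(cfg, data_dir, art_dir, res),
      "train" = .stage_train(cfg, art_dir, res),
      "evaluate" = .stage_evaluate(cfg, art_dir, res),
      "permute" = .stage_permute(cfg, art_dir, res),
      "explain" = .stage_explain(cfg, art_dir, res))
    timings[[st]] <- round(as.numeric(Sys.time() - t1, units = "secs"), 2)
  }
  manifest <- list(seed = cfg$seed, mode = cfg$mode, stages = stages,
                   timings = timings,
                   total_secs = round(as.numeric(Sys.time() - t0,
                                                 units = "secs"), 2),
                   artifacts = list.files(art_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

.need <- function(res, art_dir, name, stage_hint) {
  if (!is.null(res[[name]])) return(res[[name]])
  path <- file.path(art_dir, paste0(name, ".rds"))
  if (!file.exists(path)) {
    stop("missing upstream artifact '", name, "': run stage '",
         stage_hint, "' first")
  }
  readRDS(path)
}

.stage_simulate <- function(cfg, data_dir, res) {
  preset <- if (!is.null(cfg$preset)) cfg$preset
            else if (cfg$mode == "yeast") "yeastlike" else "humanlike"
  sc <- sim_config(
    preset = preset,
    n_genes = if (is.null(cfg$n_genes)) 1000L else cfg$n_genes,
    n_tfs = if (is.null(cfg$n_tfs)) 10L else cfg$n_tfs,
    n_samples = if (is.null(cfg$n_samples)) 10L else cfg$n_samples,
    seed = .stage_seed(cfg$seed, "simulate"))
  res$truth <- simulate_dataset(sc, data_dir)
  res
}

.stage_features <- function(cfg, data_dir, art_dir, res) {
  if (!file.exists(file.path(data_dir, "dataset.yaml"))) {
    stop("missing upstream dataset: run stage 'simulate' first")
  }
  ds <- load_dataset(data_dir)
  scheme <- bin_scheme(ds$manifest$mode,
                       enhancer_scheme = cfg$enhancer_scheme)
  fm <- build_feature_matrix(ds, scheme)
  if (!identical(cfg$feature_subset, "full")) {
    fm <- select_feature_subset(fm, cfg$feature_subset)
  }
  labels <- build_response_labels(ds$de_tables, ds$tss$gene_id,
                                  rule = ds$manifest$de_rule,
                                  tf_genes = ds$tf_genes,
                                  padj_max = cfg$thresholds$padj_max,
                                  lfc_min = cfg$thresholds$lfc_min)
  regions <- dataset_regions(ds, scheme)
  bound <- bound_gene_set(ds$peaks, regions, min_signal = 3)
  res$fm <- fm; res$labels <- labels; res$bound <- bound
  saveRDS(fm, file.path(art_dir, "fm.rds"))
  saveRDS(labels, file.path(art_dir, "labels.rds"))
  saveRDS(bound, file.path(art_dir, "bound.rds"))
  write_tsv_table(labels$tab, file.path(art_dir, "labels.tsv"))
  res
}

.stage_train <- function(cfg, art_dir, res) {
  fm <- .need(res, art_dir, "fm", "build-features")
  labels <- .need(res, art_dir, "labels", "build-features")
  tfs <- unique(fm$instances$tf_id)
  assignment <- make_tf_folds(tfs, min(cfg$fold_count, length(tfs)),
                              seed = .stage_seed(cfg$seed, "folds"))
  hp <- do.call(xgb_hyperparams, cfg$hyperparams)
  cv <- cross_validate(fm, labels_for_instances(labels, fm), assignment,
                       hp, seed = .stage_seed(cfg$seed, "train"))
  res$fm <- fm; res$labels <- labels; res$cv <- cv
  saveRDS(cv, file.path(art_dir, "cv.rds"))
  write_tsv_table(cv$predictions, file.path(art_dir, "predictions.tsv"))
  res
}

.stage_evaluate <- function(cfg, art_dir, res) {
  cv <- .need(res, art_dir, "cv", "train")
  labels <- .need(res, art_dir, "labels", "build-features")
  pr <- pr_by_tf(cv$predictions, labels)
  res$cv <- cv; res$labels <- labels
  res$pr <- pr
  res$efficacy <- efficacy_report(pr, labels)
  write_tsv_table(pr, file.path(art_dir, "pr_by_tf.tsv"))
  write_tsv_table(res$efficacy, file.path(art_dir, "efficacy.tsv"))
  saveRDS(pr, file.path(art_dir, "pr.rds"))
  res
}

.stage_permute <- function(cfg, art_dir, res) {
  fm <- .need(res, art_dir, "fm", "build-features")
  labels <- .need(res, art_dir, "labels", "build-features")
  cv <- .need(res, art_dir, "cv", "train")
  pr <- .need(res, art_dir, "pr", "evaluate")
  hp <- do.call(xgb_hyperparams, cfg$hyperparams)
  null <- permutation_null(fm, labels, cv$assignment,
                           n_perm = cfg$permutation_count,
                           seed = .stage_seed(cfg$seed, "permute"),
                           hyperparams = hp)
  lsd <- fit_lsd(null$sd, labels$fractions,
                 responder_floor = cfg$thresholds$responder_floor)
  sig <- significance_table(pr, null, lsd,
                            responder_floor = cfg$thresholds$responder_floor,
                            significance_p = cfg$thresholds$significance_p)
  res$fm <- fm; res$labels <- labels; res$cv <- cv; res$pr <- pr
  res$null <- null; res$lsd <- lsd; res$significance <- sig
  saveRDS(null, file.path(art_dir, "null.rds"))
  write_tsv_table(sig, file.path(art_dir, "significance.tsv"))
  res
}

.stage_explain <- function(cfg, art_dir, res) {
  fm <- .need(res, art_dir, "fm", "build-features")
  labels <- .need(res, art_dir, "labels", "build-features")
  cv <- .need(res, art_dir, "cv", "train")
  bound <- .need(res, art_dir, "bound", "build-features")
  attr <- compute_attributions(cv, fm)
  groups <- gene_groups(labels, bound)
  infl <- suppressWarnings(signed_sums(attr, fm, groups))
  prof <- positional_profile(attr, fm,
                             stats::setNames(lapply(names(groups), function(tf) {
                               groups[[tf]]$bound
                             }), names(groups)))
  res$fm <- fm; res$labels <- labels; res$cv <- cv
  res$attr <- attr; res$influence <- infl; res$profile <- prof
  write_tsv_table(infl, file.path(art_dir, "influence.tsv"))
  write_tsv_table(data.frame(tf_id = rownames(prof), prof,
                             check.names = FALSE),
                  file.path(art_dir, "positional_profile.tsv"))
  res
}
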