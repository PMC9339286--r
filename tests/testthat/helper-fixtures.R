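# Shared fixtures, built once per test session and cached.
.fx_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx_env[[name]])) assign(name, builder(), envir = .fx_env)
  get(name, envir = .fx_env)
}

# simulate -> load -> features -> labels -> CV (per subset) -> bound sets
sim_run <- function(preset, n_genes, n_tfs, seed, folds, nrounds,
                    subsets = "full") {
  dir <- file.path(tempdir(),
                   sprintf("fx_%s_%d_%d_%d", preset, n_genes, n_tfs, seed))
  truth <- simulate_dataset(
    sim_config(preset, n_genes = n_genes, n_tfs = n_tfs, seed = seed), dir)
  ds <- load_dataset(dir)
  fm <- build_feature_matrix(ds)
  labels <- build_response_labels(ds$de_tables, ds$tss$gene_id,
                                  rule = "de", tf_genes = ds$tf_genes)
  y <- labels_for_instances(labels, fm)
  assignment <- make_tf_folds(unique(fm$instances$tf_id), folds,
                              seed = seed + 1L)
  runs <- lapply(stats::setNames(subsets, subsets), function(s) {
    f2 <- select_feature_subset(fm, s)
    cv <- cross_validate(f2, y, assignment,
                         xgb_hyperparams(nrounds = nrounds),
                         seed = seed + 2L)
    list(cv = cv, fm = f2, pr = pr_by_tf(cv$predictions, labels))
  })
  regions <- dataset_regions(ds)
  list(truth = truth, ds = ds, fm = fm, labels = labels, y = y,
       assignment = assignment, runs = runs, regions = regions,
       bound = bound_gene_set(ds$peaks, regions, min_signal = 3))
}

yeast_fx <- function() {
  fixture("yeast", function() {
    sim_run("yeastlike", 800L, 8L, seed = 11L, folds = 8L, nrounds = 100L)
  })
}

yeast_attr <- function() {
  fixture("yeast_attr", function() {
    fx <- yeast_fx()
    compute_attributions(fx$runs$full$cv, fx$runs$full$fm)
  })
}

human_fx <- function() {
  fixture("human", function() {
    sim_run("humanlike", 800L, 8L, seed = 13L, folds = 8L, nrounds = 100L,
            subsets = c("full", "gex_only", "binding_only"))
  })
}

human_attr <- function() {
  fixture("human_attr", function() {
    fx <- human_fx()
    compute_attributions(fx$runs$full$cv, fx$runs$full$fm)
  })
}

# small booster on random data, for SHAP engine checks
toy_booster <- function(n = 400, p = 4, nrounds = 5, max_depth = 2,
                        seed = 1, min_child_weight = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, min(2, p)]))
  d <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = 0.4, nthread = 1, seed = 1,
                  min_child_weight = min_child_weight),
    data = d, nrounds = nrounds, verbose = 0)
  list(booster = booster, X = X, y = y)
}
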