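# Per-endpoint QSAR training: Bayesian hyperparameter optimization of a
# class-weighted random forest, scored by the Matthews correlation
# coefficient averaged over stratified cross-validation folds, followed by
# one round of permutation-importance feature selection and MCC-based model
# gating.

.rf_space <- list(
  num_trees = c(100, 1000),       # integer
  max_depth = c(3, 21),           # 21 decodes to "unlimited"
  min_node_size = c(1, 10),       # integer
  mtry_mode = c(1, 3),            # 1 sqrt(p), 2 log2(p), 3 fraction
  mtry_frac = c(0.1, 1),
  class_weight = c(1, 3))         # 1 none, 2 balanced, 3 balanced_sqrt

.decode_config <- function(u) {
  s <- .rf_space
  dec <- function(nm, int = TRUE) {
    lo <- s[[nm]][1L]; hi <- s[[nm]][2L]
    v <- lo + u[[nm]] * (hi - lo)
    if (int) as.integer(round(v)) else v
  }
  list(num_trees = dec("num_trees"),
       max_depth = { d <- dec("max_depth"); if (d >= 21L) 0L else d },
       min_node_size = dec("min_node_size"),
       mtry_mode = c("sqrt", "log2", "frac")[dec("mtry_mode")],
       mtry_frac = dec("mtry_frac", int = FALSE),
       class_weight = c("none", "balanced", "balanced_sqrt")[dec("class_weight")])
}

.config_mtry <- function(cfg, p) {
  m <- switch(cfg$mtry_mode,
              sqrt = sqrt(p),
              log2 = log2(p),
              frac = cfg$mtry_frac * p)
  max(1L, min(p, as.integer(round(m))))
}

.config_weights <- function(cfg, y) {
  tab <- table(y)
  w <- switch(cfg$class_weight,
              none = c(1, 1),
              balanced = as.numeric(sum(tab) / (2 * tab)),
              balanced_sqrt = sqrt(as.numeric(sum(tab) / (2 * tab))))
  stats::setNames(w, names(tab))
}

.fit_rf <- function(X, y, cfg, seed, probability = TRUE) {
  ranger::ranger(x = X, y = y,
                 num.trees = cfg$num_trees,
                 max.depth = cfg$max_depth,
                 min.node.size = cfg$min_node_size,
                 mtry = .config_mtry(cfg, ncol(X)),
                 class.weights = .config_weights(cfg, y),
                 probability = probability,
                 importance = "impurity",
                 seed = as.integer(seed), num.threads = 1L,
                 verbose = FALSE)
}

.predict_class <- function(fit, X) {
  pr <- stats::predict(fit, data = X, num.threads = 1L)$predictions
  if (is.matrix(pr)) {
    as.integer(pr[, "1"] > 0.5)
  } else {
    as.integer(as.character(pr))
  }
}

.predict_prob <- function(fit, X) {
  pr <- stats::predict(fit, data = X, num.threads = 1L)$predictions
  stopifnot(is.matrix(pr))
  unname(pr[, "1"])
}

# stratified fold assignment, deterministic under the current RNG state
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    members <- which(y == cl)
    folds[members] <- sample(rep_len(seq_len(k), length(members)))
  }
  folds
}

# mean MCC over stratified CV folds for one configuration
.cv_mcc <- function(X, y, cfg, folds, seed) {
  k <- max(folds)
  mccs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    fit <- .fit_rf(X[tr, , drop = FALSE], y[tr], cfg,
                   seed = seed + f, probability = FALSE)
    pred <- .predict_class(fit, X[!tr, , drop = FALSE])
    mccScore(confusionCounts(as.integer(as.character(y[!tr])), pred))
  }, numeric(1))
  mean(mccs)
}

# expected improvement of candidate means/sds over the current best value
.expected_improvement <- function(mu, sigma, best) {
  sigma <- pmax(sigma, 1e-9)
  z <- (mu - best) / sigma
  (mu - best) * stats::pnorm(z) + sigma * stats::dnorm(z)
}

# Bayesian optimization over the RF space: Latin-hypercube initial design,
# Gaussian-process surrogate (kernlab), expected-improvement acquisition
# over a seeded random candidate pool.
.bo_optimize <- function(X, y, n_iter, cv_folds, seed) {
  dims <- names(.rf_space)
  n_init <- max(4L, min(8L, n_iter - 2L))
  if (n_iter <= n_init) n_init <- max(1L, n_iter - 1L)
  set.seed(seed)
  folds <- .stratified_folds(y, cv_folds)
  design <- lhs::maximinLHS(n_init, length(dims))
  colnames(design) <- dims
  evals <- data.frame()
  scores <- numeric(0)
  eval_point <- function(u) {
    cfg <- .decode_config(as.list(u))
    .cv_mcc(X, y, cfg, folds, seed)
  }
  for (i in seq_len(n_init)) {
    scores <- c(scores, eval_point(design[i, ]))
  }
  pts <- design
  while (nrow(pts) < n_iter) {
    set.seed(seed + nrow(pts))
    cand <- matrix(stats::runif(200 * length(dims)), 200, length(dims),
                   dimnames = list(NULL, dims))
    mu_sd <- tryCatch({
      gp <- kernlab::gausspr(pts, scores, variance.model = TRUE,
                             kpar = list(sigma = 1), var = 0.01,
                             scaled = FALSE)
      list(mu = as.numeric(kernlab::predict(gp, cand)),
           sd = as.numeric(kernlab::predict(gp, cand, type = "sdeviation")))
    }, error = function(e) NULL)
    nxt <- if (is.null(mu_sd)) {
      cand[1L, ]
    } else {
      ei <- .expected_improvement(mu_sd$mu, mu_sd$sd, max(scores))
      cand[which.max(ei), ]
    }
    pts <- rbind(pts, nxt)
    scores <- c(scores, eval_point(nxt))
  }
  best <- which.max(scores)
  list(config = .decode_config(as.list(pts[best, ])),
       mcc_cv = scores[best],
       trace = data.frame(iteration = seq_along(scores), mcc_cv = scores))
}

.metrics_row <- function(fit, Xtr, ytr, Xte, yte, mcc_cv, n_features) {
  ptr <- .predict_class(fit, Xtr)
  pte <- .predict_class(fit, Xte)
  cm_tr <- confusionCounts(as.integer(as.character(ytr)), ptr)
  cm_te <- confusionCounts(as.integer(as.character(yte)), pte)
  data.frame(mcc_train = mccScore(cm_tr),
             bacc_train = balancedAccuracy(cm_tr),
             mcc_cv = mcc_cv,
             mcc_test = mccScore(cm_te),
             bacc_test = balancedAccuracy(cm_te),
             n_features = as.integer(n_features))
}

.feature_matrices <- function(split, scheme, features = NULL) {
  if (is.null(features)) {
    Xtr <- featurizeCompounds(compounds(trainSet(split)), scheme)
    Xte <- featurizeCompounds(compounds(testSet(split)), scheme)
  } else {
    Xtr <- features[[1L]]; Xte <- features[[2L]]
  }
  list(train = Xtr, test = Xte)
}

#' Train an optimized classifier for one endpoint
#'
#' Runs Bayesian hyperparameter optimization (`nIter` evaluations) of a
#' class-weighted random forest over number of trees, depth, node size,
#' feature subsampling and class-weighting mode. Each configuration is
#' scored by the mean MCC over `cvFolds` stratified cross-validation folds
#' on the training partition; the best configuration is refit on the full
#' training set and evaluated on train and test. When several feature
#' schemes are given, each is optimized separately and the scheme with the
#' best cross-validated MCC is kept.
#'
#' Constant (zero-variance) feature columns of the training partition are
#' removed before optimization.
#'
#' @param split a [TrainTestSplit].
#' @param schemes feature scheme(s) to try (see [featurizeCompounds()]).
#' @param nIter number of optimization iterations (default 20).
#' @param cvFolds number of cross-validation folds (default 10).
#' @param seed integer seed; identical seeds give identical models.
#' @param features optional precomputed feature matrices, a named list
#'   `list(scheme = list(train, test))`, to avoid refeaturizing.
#' @return an [EndpointModel].
#' @export
trainEndpointModel <- function(split, schemes = c("descriptors",
                                                  "circular_fingerprint"),
                               nIter = 20L, cvFolds = 10L, seed = 1L,
                               features = NULL) {
  stopifnot(is(split, "TrainTestSplit"), nIter >= 2L, cvFolds >= 2L)
  tr <- trainSet(split)
  if (nPos(tr) == 0L || nPos(tr) == nTotal(tr))
    stop("training partition must contain both classes")
  if (min(nPos(tr), nTotal(tr) - nPos(tr)) < cvFolds)
    stop("fewer than cvFolds (", cvFolds, ") minority-class compounds in ",
         "train; use fewer folds or more data")
  ytr <- factor(labels01(tr), levels = c("0", "1"))
  yte <- factor(labels01(testSet(split)), levels = c("0", "1"))
  best <- NULL
  for (scheme in schemes) {
    fm <- .feature_matrices(split, scheme, features[[scheme]])
    keep <- which(apply(fm$train, 2L, function(v) stats::var(v) > 0))
    Xtr <- fm$train[, keep, drop = FALSE]
    sseed <- childSeed(seed, paste0(endpointName(tr), ":", scheme))
    opt <- .bo_optimize(Xtr, ytr, n_iter = nIter, cv_folds = cvFolds,
                        seed = sseed)
    if (is.null(best) || opt$mcc_cv > best$mcc_cv) {
      best <- list(scheme = scheme, opt = opt, mcc_cv = opt$mcc_cv,
                   Xtr = Xtr, Xte = fm$test[, keep, drop = FALSE],
                   seed = sseed)
    }
  }
  fit <- .fit_rf(best$Xtr, ytr, best$opt$config, seed = best$seed)
  metrics <- .metrics_row(fit, best$Xtr, ytr, best$Xte, yte,
                          mcc_cv = best$mcc_cv, n_features = ncol(best$Xtr))
  new("EndpointModel",
      endpoint = endpointName(tr), scheme = best$scheme,
      features = colnames(best$Xtr),
      hyperparameters = best$opt$config,
      fit = fit, metrics = metrics, seed = as.integer(best$seed))
}

#' Permutation-importance feature selection
#'
#' Computes permutation importance of every feature on the training
#' partition (`nRepeats` seeded permutations per feature, scored by the
#' drop in MCC), retains features with mean importance strictly above zero,
#' and refits the model with the winning hyperparameters on the reduced
#' feature set. One selection round. If no feature has positive importance
#' the single most important feature is kept, with a warning.
#'
#' @param model an [EndpointModel] from [trainEndpointModel()].
#' @param split the [TrainTestSplit] the model was trained on.
#' @param nRepeats permutations per feature (default 10).
#' @param features optional precomputed `list(train, test)` feature
#'   matrices for the model's scheme.
#' @return the refitted [EndpointModel] with updated features and metrics
#'   (`mcc_cv` is carried over from optimization).
#' @export
selectFeaturesPermutation <- function(model, split, nRepeats = 10L,
                                      features = NULL) {
  stopifnot(is(model, "EndpointModel"), is(split, "TrainTestSplit"))
  fm <- .feature_matrices(split, model@scheme, features)
  Xtr <- fm$train[, model@features, drop = FALSE]
  Xte <- fm$test[, model@features, drop = FALSE]
  ytr <- factor(labels01(trainSet(split)), levels = c("0", "1"))
  yte <- factor(labels01(testSet(split)), levels = c("0", "1"))
  ytr_int <- as.integer(as.character(ytr))
  base_pred <- .predict_class(model@fit, Xtr)
  base_mcc <- mccScore(confusionCounts(ytr_int, base_pred))
  p <- ncol(Xtr)
  imp <- matrix(0, nRepeats, p, dimnames = list(NULL, colnames(Xtr)))
  for (r in seq_len(nRepeats)) {
    set.seed(model@seed + 1000L + r)
    perm <- sample(nrow(Xtr))
    for (j in seq_len(p)) {
      Xp <- Xtr
      Xp[, j] <- Xp[perm, j]
      pred <- .predict_class(model@fit, Xp)
      imp[r, j] <- base_mcc - mccScore(confusionCounts(ytr_int, pred))
    }
  }
  mean_imp <- colMeans(imp)
  keep <- names(mean_imp)[mean_imp > 0]
  if (length(keep) == 0L) {
    warning("no feature had positive permutation importance; ",
            "keeping the single best feature")
    # rank ties (e.g. fully redundant separable features) by the forest's
    # impurity importance
    impurity <- model@fit$variable.importance[names(mean_imp)]
    impurity[is.na(impurity)] <- 0
    keep <- names(mean_imp)[order(-mean_imp, -impurity)][1L]
  }
  keep <- colnames(Xtr)[colnames(Xtr) %in% keep]  # preserve column order
  Xtr2 <- Xtr[, keep, drop = FALSE]
  Xte2 <- Xte[, keep, drop = FALSE]
  fit <- .fit_rf(Xtr2, ytr, model@hyperparameters, seed = model@seed)
  metrics <- .metrics_row(fit, Xtr2, ytr, Xte2, yte,
                          mcc_cv = model@metrics$mcc_cv,
                          n_features = length(keep))
  imp_tbl <- data.frame(feature = colnames(Xtr), importance = mean_imp,
                        row.names = NULL)
  out <- new("EndpointModel", endpoint = model@endpoint,
             scheme = model@scheme, features = keep,
             hyperparameters = model@hyperparameters, fit = fit,
             metrics = metrics, seed = model@seed)
  attr(out, "importance") <- imp_tbl[order(-imp_tbl$importance), ]
  out
}

#' Gate models by MCC criteria
#'
#' Keeps endpoints whose cross-validated and test MCC both strictly exceed
#' the thresholds (default 0.30 / 0.30).
#'
#' @param metrics data.frame with columns `endpoint`, `mcc_cv`, `mcc_test`
#'   (one row per endpoint), e.g. from [metricsTable()].
#' @param mccCv,mccTest gating thresholds (strict inequalities).
#' @return character vector of surviving endpoint names.
#' @examples
#' m <- data.frame(endpoint = c("SR-HSE", "NR-AR"),
#'                 mcc_cv = c(0.27, 0.58), mcc_test = c(0.23, 0.70))
#' gateModels(m)  # "NR-AR"
#' @export
gateModels <- function(metrics, mccCv = 0.30, mccTest = 0.30) {
  stopifnot(all(c("endpoint", "mcc_cv", "mcc_test") %in% colnames(metrics)))
  metrics$endpoint[metrics$mcc_cv > mccCv & metrics$mcc_test > mccTest]
}

#' Metrics report for a set of models
#'
#' @param models list of [EndpointModel] objects.
#' @param datasets optional list of [EndpointDataset] objects (same order)
#'   to append the imbalance ratio column.
#' @return data.frame with one row per endpoint: MCC/BACC on train, CV and
#'   test, the number of selected features and, when datasets are given,
#'   the `n_pos/n_total` ratio.
#' @export
metricsTable <- function(models, datasets = NULL) {
  tab <- do.call(rbind, lapply(models, function(m)
    cbind(data.frame(endpoint = m@endpoint, scheme = m@scheme,
                     stringsAsFactors = FALSE), modelMetrics(m))))
  rownames(tab) <- NULL
  if (!is.null(datasets)) {
    cnt <- endpointCounts(datasets)
    tab$ratio <- cnt$ratio[match(tab$endpoint, cnt$endpoint)]
  }
  tab
}

#' Persist / restore an endpoint model
#'
#' The archive stores the fitted classifier state, hyperparameters,
#' selected features, metrics, seed and toolkit versions; predictions from
#' a restored model are identical to the in-memory model.
#'
#' @param model an [EndpointModel].
#' @param path file path (one archive per endpoint).
#' @return `saveEndpointModel` returns `path` invisibly;
#'   `readEndpointModel` returns the [EndpointModel].
#' @export
saveEndpointModel <- function(model, path) {
  stopifnot(is(model, "EndpointModel"))
  payload <- list(model = model,
                  versions = list(
                    package = as.character(utils::packageVersion("MetaboBiP")),
                    ranger = as.character(utils::packageVersion("ranger")),
                    R = R.version.string))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveEndpointModel
#' @export
readEndpointModel <- function(path) {
  payload <- readRDS(path)
  stopifnot(is(payload$model, "EndpointModel"))
  payload$model
}
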