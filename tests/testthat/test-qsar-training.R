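test_that("a planted structure-activity rule is learned almost perfectly", {
  m <- small_model()
  expect_s4_class(m, "EndpointModel")
  mm <- modelMetrics(m)
  expect_gt(mm$mcc_cv, 0.8)
  expect_gt(mm$mcc_test, 0.3)
  expect_true(all(unlist(mm[c("mcc_train", "mcc_cv", "mcc_test")]) <= 1))
  expect_gte(mm$n_features, 1L)
})

test_that("training is deterministic under a fixed seed", {
  sp <- small_split()
  m1 <- trainEndpointModel(sp, schemes = "descriptors", nIter = 4L,
                           cvFolds = 3L, seed = 99)
  m2 <- trainEndpointModel(sp, schemes = "descriptors", nIter = 4L,
                           cvFolds = 3L, seed = 99)
  expect_identical(m1@hyperparameters, m2@hyperparameters)
  expect_identical(modelMetrics(m1), modelMetrics(m2))
  X <- featurizeCompounds(compounds(testSet(sp)), "descriptors")
  expect_identical(
    MetaboBiP:::.predict_prob(m1@fit, X[, m1@features, drop = FALSE]),
    MetaboBiP:::.predict_prob(m2@fit, X[, m2@features, drop = FALSE]))
})

test_that("permuted labels give chance-level cross-validated MCC", {
  sp <- small_split()
  feats <- list(descriptors = list(
    featurizeCompounds(compounds(trainSet(sp)), "descriptors"),
    featurizeCompounds(compounds(testSet(sp)), "descriptors")))
  mccs <- vapply(1:5, function(r) {
    set.seed(1000 + r)
    tr <- trainSet(sp)
    shuffled <- new("EndpointDataset", endpoint = tr@endpoint,
                    compounds = tr@compounds,
                    labels = sample(tr@labels))
    sp_null <- new("TrainTestSplit", train = shuffled, test = testSet(sp),
                   seed = sp@seed)
    m <- trainEndpointModel(sp_null, schemes = "descriptors", nIter = 3L,
                            cvFolds = 3L, seed = r, features = feats)
    modelMetrics(m)$mcc_cv
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.15)
  expect_true(all(abs(mccs) < 0.3))
})

test_that("permutation importance keeps planted features and drops noise", {
  set.seed(7)
  n <- 300; p <- 60
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("d%03d", 1:p)))
  X[, "d060"] <- 1                      # constant feature: importance 0
  y <- as.integer(rowSums(X[, 1:5]) > 0)  # linear-threshold rule on d001-d005
  ids <- sprintf("c%03d", 1:n)
  cs <- standardizeStructures(stats::setNames(rep("CCO", n), ids))
  cs@data$canonical_structure <- paste0("C", strrep("C", 1:n))  # unique
  tr_i <- 1:240; te_i <- 241:300
  mk <- function(i) new("EndpointDataset", endpoint = "NR-AR",
                        compounds = cs[i], labels = y[i])
  sp <- new("TrainTestSplit", train = mk(tr_i), test = mk(te_i),
            seed = 1L)
  rownames(X) <- ids
  feats <- list(train = X[tr_i, ], test = X[te_i, ])
  m <- trainEndpointModel(sp, schemes = "descriptors", nIter = 4L,
                          cvFolds = 3L, seed = 5,
                          features = list(descriptors = feats))
  # the all-constant feature is already recognized as uninformative at
  # training time
  expect_false("d060" %in% selectedFeatures(m))
  m2 <- selectFeaturesPermutation(m, sp, nRepeats = 10L, features = feats)
  kept <- selectedFeatures(m2)
  # independent check: the five planted features carry all the signal
  expect_true(all(sprintf("d%03d", 1:5) %in% kept))
  expect_lte(length(kept), length(selectedFeatures(m)))
  expect_false("d060" %in% kept)
  expect_identical(modelMetrics(m2)$n_features, length(kept))
  imp <- attr(m2, "importance")
  expect_true(all(imp$importance[match(sprintf("d%03d", 1:5),
                                       imp$feature)] > 0))
})

test_that("model gating applies strict MCC thresholds monotonically", {
  metrics <- data.frame(
    endpoint = c("SR-HSE", "NR-AR", "edge"),
    mcc_cv = c(0.27, 0.58, 0.30),
    mcc_test = c(0.23, 0.70, 0.50))
  expect_identical(gateModels(metrics), "NR-AR")
  # raising either threshold never adds endpoints
  set.seed(3)
  m <- data.frame(endpoint = paste0("e", 1:30),
                  mcc_cv = runif(30, -0.2, 0.9),
                  mcc_test = runif(30, -0.2, 0.9))
  for (i in 1:20) {
    t1 <- runif(1, -0.2, 0.9); t2 <- runif(1, -0.2, 0.9)
    g_lo <- gateModels(m, t1, t2)
    g_hi <- gateModels(m, t1 + 0.1, t2 + 0.05)
    expect_true(all(g_hi %in% g_lo))
  }
})

test_that("persisted models reproduce their in-memory predictions exactly", {
  m <- small_model()
  sp <- small_split()
  path <- tempfile(fileext = ".rds")
  saveEndpointModel(m, path)
  m2 <- readEndpointModel(path)
  X <- featurizeCompounds(compounds(testSet(sp)), "descriptors")
  p1 <- MetaboBiP:::.predict_prob(m@fit, X[, selectedFeatures(m), drop = FALSE])
  p2 <- MetaboBiP:::.predict_prob(m2@fit, X[, selectedFeatures(m2), drop = FALSE])
  expect_identical(p1, p2)
  expect_identical(modelMetrics(m2), modelMetrics(m))
  unlink(path)
})

test_that("both feature representations compete and the better one is kept", {
  sp <- small_split()
  m <- trainEndpointModel(sp, schemes = c("descriptors",
                                          "circular_fingerprint"),
                          nIter = 3L, cvFolds = 3L, seed = 17)
  expect_true(featureScheme(m) %in% c("descriptors", "circular_fingerprint"))
  expect_gt(modelMetrics(m)$mcc_cv, 0.5)
})

test_that("training guards its preconditions", {
  sp <- small_split()
  expect_error(trainEndpointModel(sp, schemes = "descriptors", nIter = 4L,
                                  cvFolds = 50L, seed = 1),
               "fewer than cvFolds")
})
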