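panel_from <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  MetabolitePanel(m, subjectsAsRows = TRUE)
}

test_that("the missingness filter drops strictly above the threshold", {
  m <- matrix(1, 100, 3, dimnames = list(sprintf("s%03d", 1:100),
                                         c("drop40", "keep0", "keep33")))
  m[1:40, "drop40"] <- NA
  m[1:33, "keep33"] <- NA
  panel <- MetabolitePanel(m, subjectsAsRows = TRUE)
  out <- filterMissingness(panel)
  expect_identical(rownames(out), c("keep0", "keep33"))
})

test_that("imputation fills a tenth of the observed minimum", {
  p <- panel_from(a = c(0.5, NA, 2, NA), b = c(1, 2, 3, 4))
  out <- imputeMinFraction(p)
  a <- abundances(out)
  expect_identical(unname(a["a", c(2, 4)]), c(0.05, 0.05))
  expect_identical(a["b", ], abundances(p)["b", ])   # untouched
  expect_identical(abundances(imputeMinFraction(out)), a)  # no-op when complete
  pz <- panel_from(z = c(0, NA, 1))
  expect_warning(oz <- imputeMinFraction(pz), "zero")
  expect_identical(unname(abundances(oz)["z", 2]), 0)
  p_allna <- panel_from(q = c(NA_real_, NA_real_), r = c(1, 2))
  expect_error(imputeMinFraction(p_allna), "all-missing")
})

test_that("min-max scaling maps each metabolite to [0, 1]", {
  p <- panel_from(a = c(2, 4, 6), b = c(3, 3, 3), c = c(0, 0.5, 1))
  out <- abundances(minMaxScale(p))
  expect_identical(unname(out["a", ]), c(0, 0.5, 1))
  expect_identical(unname(out["b", ]), c(0, 0, 0))   # constant degenerates to 0
  expect_identical(unname(out["c", ]), c(0, 0.5, 1)) # already scaled: identity
})

test_that("the variance filter removes the floor of the lowest decile", {
  set.seed(1)
  m20 <- matrix(runif(20 * 30), 30, 20,
                dimnames = list(NULL, sprintf("m%02d", 1:20)))
  m20[, "m07"] <- 0.5                       # zero variance
  m20[, "m13"] <- 0.5 + seq(0, 1e-3, length.out = 30)  # tiny variance
  p <- MetabolitePanel(m20, subjectsAsRows = TRUE)
  out <- dropLowVariance(p)
  expect_identical(nrow(out), 18L)          # floor(0.1 * 20) = 2 removed
  expect_false(any(c("m07", "m13") %in% rownames(out)))
  # 9 metabolites: floor(0.9) = 0 removed
  p9 <- p[1:9, ]
  expect_identical(rownames(dropLowVariance(p9)), rownames(p9))
  # a constant column is always among the removed whenever any are
  for (s in 1:5) {
    set.seed(s)
    mm <- matrix(runif(12 * 25), 25, 12,
                 dimnames = list(NULL, sprintf("v%02d", 1:12)))
    mm[, 5] <- 1
    pp <- dropLowVariance(MetabolitePanel(mm, subjectsAsRows = TRUE))
    expect_false("v05" %in% rownames(pp))
  }
})

test_that("correlation pruning is greedy, deterministic and complete", {
  set.seed(5)
  x <- stats::runif(50)
  p <- panel_from(a = x, b = x * 2 + 1, c = stats::runif(50))
  out <- pruneCorrelated(p)
  expect_identical(sort(rownames(out)), c("a", "c"))  # one duplicate survives
  # three mutually duplicated columns collapse to one
  p3 <- panel_from(a = x, b = x + 10, c = 3 * x, d = stats::runif(50))
  out3 <- pruneCorrelated(p3)
  expect_identical(sort(rownames(out3)), c("a", "d"))
  # independent columns at n = 200 all survive
  set.seed(11)
  big <- matrix(stats::runif(200 * 15), 200, 15,
                dimnames = list(NULL, sprintf("n%02d", 1:15)))
  pb <- MetabolitePanel(big, subjectsAsRows = TRUE)
  expect_identical(nrow(pruneCorrelated(pb)), 15L)
})

test_that("the composed pipeline cleans the fixture as hand-enumerated", {
  panel <- prep_fixture()
  out <- prepareMetabolitePanel(panel)
  expect_identical(rownames(out), prep_fixture_survivors)
  a <- abundances(out)
  expect_false(anyNA(a))
  expect_true(all(a >= 0 & a <= 1))
  # imputed cells of M02 (observed min 2 -> fill 0.2) become the scaled zero
  expect_identical(unname(a["M02", c(3, 7, 11, 15, 18, 20)]), rep(0, 6))
  # subjects are never dropped
  expect_identical(colnames(out), colnames(panel))
})

test_that("each step and the pipeline are pure and idempotent where guaranteed", {
  panel <- prep_fixture()
  once <- prepareMetabolitePanel(panel)
  # fewer than 10 metabolites remain, so the decile filter is inert and
  # the whole pipeline is idempotent
  twice <- prepareMetabolitePanel(once)
  expect_identical(abundances(twice), abundances(once))
  expect_identical(rownames(twice), rownames(once))
  # per-step idempotence on the cleaned panel
  expect_identical(abundances(minMaxScale(once)), abundances(once))
  expect_identical(rownames(pruneCorrelated(once)), rownames(once))
  expect_identical(rownames(filterMissingness(once)), rownames(once))
})

test_that("cleaned panels satisfy the pipeline postconditions", {
  for (s in 1:3) {
    coh <- syntheticCohort(nSubjects = 60, nMetabolites = 25, seed = 400 + s,
                           missingRate = 0.2)
    out <- suppressWarnings(prepareMetabolitePanel(coh$panel))
    a <- abundances(out)
    expect_false(anyNA(a))
    expect_true(all(a >= 0 & a <= 1))
    cc <- abs(stats::cor(t(a)))
    cc[is.na(cc)] <- 0
    diag(cc) <- 0
    expect_lte(max(cc), 0.90)
    expect_lte(nrow(out), nrow(coh$panel))
    expect_identical(colnames(out), colnames(coh$panel))
  }
})
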