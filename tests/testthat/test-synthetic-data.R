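test_that("the library meets its positive fraction and the planted rule exactly", {
  lib <- syntheticLibrary(nCompounds = 1000, positiveFraction = 0.10,
                          labelNoise = 0, seed = 5)
  expect_length(lib$smiles, 1000L)
  n_pos <- sum(lib$records$label)
  expect_gte(n_pos, 80L)
  expect_lte(n_pos, 120L)
  # with zero noise the labels equal the construction truth
  expect_identical(lib$records$label, unname(lib$truth))
  # independent oracle: a substructure matcher reproduces every label
  cs <- standardizeStructures(lib$smiles)
  expect_true(all(isValid(cs)))
  mols <- MetaboBiP:::.ob_parse(unname(canonicalSmiles(cs)))
  hits <- MetaboBiP:::.ob_smarts_count(mols, "S(=O)(=O)N")
  expect_identical(as.integer(hits > 0),
                   unname(lib$truth[compoundIds(cs)]))
})

test_that("library generation is seed-deterministic and validates its spec", {
  l1 <- syntheticLibrary(nCompounds = 200, positiveFraction = 0.2, seed = 9)
  l2 <- syntheticLibrary(nCompounds = 200, positiveFraction = 0.2, seed = 9)
  expect_identical(l1, l2)
  l3 <- syntheticLibrary(nCompounds = 200, positiveFraction = 0.2, seed = 10)
  expect_false(identical(l1$smiles, l3$smiles))
  expect_error(syntheticLibrary(nCompounds = 100, positiveFraction = 0))
  expect_error(syntheticLibrary(nCompounds = 100, labelNoise = 0.5))
})

test_that("label noise flips the stated fraction of labels", {
  lib <- syntheticLibrary(nCompounds = 1000, positiveFraction = 0.3,
                          labelNoise = 0.1, seed = 23)
  flipped <- mean(lib$records$label != lib$truth)
  expect_gt(flipped, 0.05)
  expect_lt(flipped, 0.15)
})

test_that("the cohort generator honours missingness, blocks and determinism", {
  c0 <- syntheticCohort(nSubjects = 100, nMetabolites = 24, missingRate = 0,
                        seed = 3)
  expect_false(anyNA(abundances(c0$panel)))
  c1 <- syntheticCohort(nSubjects = 100, nMetabolites = 24,
                        missingRate = 0.2, seed = 3)
  expect_gt(mean(is.na(abundances(c1$panel))), 0.15)
  expect_lt(mean(is.na(abundances(c1$panel))), 0.25)
  c2 <- syntheticCohort(nSubjects = 100, nMetabolites = 24,
                        missingRate = 0.2, seed = 3)
  expect_identical(abundances(c1$panel), abundances(c2$panel))
  expect_identical(c1$outcome, c2$outcome)
  # left-censored variant removes the low tail
  c3 <- syntheticCohort(nSubjects = 100, nMetabolites = 24,
                        missingRate = 0.2, seed = 3,
                        censoredMissingness = TRUE)
  a3 <- abundances(c3$panel)
  m1 <- a3[1, ]
  expect_true(min(m1, na.rm = TRUE) >= stats::quantile(
    abundances(c0$panel)[1, ], 0.15))
})

test_that("the latent within-block correlation matches its target", {
  coh <- syntheticCohort(nSubjects = 1000, nMetabolites = 18,
                         blockCorrelation = 0.6, missingRate = 0, seed = 12)
  z <- coh$latent
  block1 <- z[, 1:6]
  cc <- stats::cor(block1)
  off <- cc[upper.tri(cc)]
  expect_lt(max(abs(off - 0.6)), 0.05 + 0.05)   # Monte-Carlo band at n=1000
  across <- stats::cor(z[, 1], z[, 7])
  expect_lt(abs(across), 0.12)
})

test_that("every generated structure passes standardization", {
  smi <- syntheticMetaboliteStructures(nMetabolites = 30, nBioactive = 8,
                                       seed = 44)
  ann <- smi[!is.na(smi)]
  cs <- standardizeStructures(ann)
  expect_true(all(isValid(cs)))
  expect_identical(anyDuplicated(canonicalSmiles(cs)), 0L)
  # bioactive metabolites carry the planted substructure, others do not
  mols <- MetaboBiP:::.ob_parse(unname(canonicalSmiles(cs)))
  hits <- MetaboBiP:::.ob_smarts_count(mols, "S(=O)(=O)N") > 0
  bio <- compoundIds(cs) %in% attr(smi, "bioactive")
  expect_identical(unname(hits), bio)
})

test_that("a null cohort yields no planted association", {
  n_sig <- 0L
  for (s in 1:3) {
    coh <- syntheticCohort(nSubjects = 250, nMetabolites = 30,
                           plantedEffects = stats::setNames(
                             numeric(3), sprintf("met_%02d", c(1, 12, 22))),
                           missingRate = 0, seed = 700 + s)
    a <- abundances(suppressWarnings(prepareMetabolitePanel(coh$panel)))
    sb <- t(log10(pmax(a, 1e-6)))
    keep <- apply(sb, 2, stats::var) > 0
    X <- suppressWarnings(preparePredictors(sb[, keep, drop = FALSE]))
    y <- prepareOutcome(coh$outcome)
    res <- fitAssociation(X, y)
    n_sig <- n_sig + sum(res$p_value[res$metabolite != "intercept"] < 0.001)
  }
  expect_lte(n_sig, 2L)   # ~0.001 x ~25 predictors x 3 runs expected
})
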