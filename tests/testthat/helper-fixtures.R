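# Shared fixtures, built lazily and cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

# A small planted-rule library with its curated structures and split.
small_split <- function() {
  if (is.null(.fixture_env$split)) {
    lib <- syntheticLibrary(nCompounds = 300, positiveFraction = 0.15,
                            seed = 7)
    cs <- deduplicateCompounds(standardizeStructures(lib$smiles))
    ds <- assembleEndpoint(lib$records, cs, "NR-AR")
    .fixture_env$lib <- lib
    .fixture_env$dataset <- ds
    .fixture_env$split <- splitTrainTest(ds, 0.8, seed = 11)
  }
  .fixture_env$split
}

small_library <- function() { small_split(); .fixture_env$lib }
small_dataset <- function() { small_split(); .fixture_env$dataset }

# A trained + feature-selected model on the small library (descriptors).
small_model <- function() {
  if (is.null(.fixture_env$model)) {
    m <- trainEndpointModel(small_split(), schemes = "descriptors",
                            nIter = 6L, cvFolds = 5L, seed = 3)
    .fixture_env$model_pre_selection <- m
    .fixture_env$model <- suppressWarnings(
      selectFeaturesPermutation(m, small_split(), nRepeats = 5L))
  }
  .fixture_env$model
}

# The 10-metabolite x 20-subject preparation fixture with constructed
# missingness. Hand-enumerated behaviour:
#   M01  8/20 missing (0.40 > 0.33)          -> dropped by the 33% filter
#   M02  6/20 missing (0.30), observed min 2 -> kept, imputed with 0.2
#   M03  constant 5                          -> kept, scales to all-zero
#   M04  1..20                                \ Pearson r = 1, tie on mean
#   M05  2*M04 + 3                            / |r|: larger name M05 dropped
#   M06..M10 patterned, all pairwise |r| <= 0.87
# After the missingness filter 9 metabolites remain, so the lowest-decile
# variance filter removes floor(0.9) = 0 of them.
prep_fixture <- function() {
  m <- cbind(
    M01 = c(1:12, rep(NA, 8)),
    M02 = {
      v <- seq(2, 40, 2)
      v[c(3, 7, 11, 15, 18, 20)] <- NA
      v
    },
    M03 = rep(5, 20),
    M04 = 1:20,
    M05 = 2 * (1:20) + 3,
    M06 = rep(c(1, 10), 10),
    M07 = rep(c(1, 1, 10, 10), 5),
    M08 = rep(c(1, 10, 10, 1), 5),
    M09 = c(rep(1, 10), rep(10, 10)),
    M10 = c(1:10, 10:1))
  rownames(m) <- sprintf("s%02d", 1:20)
  MetabolitePanel(m, subjectsAsRows = TRUE)
}

prep_fixture_survivors <- c("M02", "M03", "M04", "M06", "M07", "M08",
                            "M09", "M10")

# A small challenge-format SDF with per-endpoint label tags. Counts for
# NR-AR, enumerated by hand:
#   C01 CCO            0        C05 OCC (duplicate structure) 1 -> conflict,
#   C02 c1ccccc1N      1             both C01/C05 dropped
#   C03 CCS(=O)(=O)N   1        C07 label missing (no tag)    -> dropped
#   C04 CCCC           0
# leaving n_total = 3 (C02, C03, C04), n_pos = 2. SR-ARE tags: C02=1, C03=0, C04=0
# -> n_total = 3, n_pos = 1.
write_mini_assay_sdf <- function(path) {
  smi <- c(C01 = "CCO", C02 = "c1ccccc1N", C03 = "CCS(=O)(=O)N",
           C04 = "CCCC", C05 = "OCC", C07 = "CC(C)O")
  sdf <- ChemmineR::smiles2sdf(smi)
  ChemmineR::datablock(sdf) <- list(
    c("NR-AR" = "0"),
    c("NR-AR" = "1", "SR-ARE" = "1"),
    c("NR-AR" = "1", "SR-ARE" = "0"),
    c("NR-AR" = "0", "SR-ARE" = "0"),
    c("NR-AR" = "1"),
    character(0))
  ChemmineR::write.SDF(sdf, path, cid = TRUE)
  path
}
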