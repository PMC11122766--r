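test_that("standardization strips salts, normalizes aromaticity and survives bad input", {
  cs <- standardizeStructures(c(a = "CCO.Cl", b = "C1=CC=CC=C1",
                                c = "c1ccccc1", d = "C1CC", e = ""))
  expect_s4_class(cs, "CompoundSet")
  can <- canonicalSmiles(cs)
  expect_identical(unname(can["a"]), "CCO")
  expect_true("salt_stripped" %in% curationFlags(cs)$a)
  # Kekule and aromatic spellings of benzene converge
  expect_identical(unname(can["b"]), unname(can["c"]))
  # unparseable and empty input: invalid, no exception
  expect_false(isValid(cs)[["d"]])
  expect_false(isValid(cs)[["e"]])
  expect_match(cs@data$note[cs@data$compound_id == "d"], "parse")
})

test_that("covalently written metal salts are disconnected, stripped and neutralized", {
  cs <- standardizeStructures(c(x = "CC(=O)O[Na]", y = "CC(=O)[O-].[Na+]"))
  can <- canonicalSmiles(cs)
  expect_identical(unname(can["x"]), "CC(=O)O")
  expect_identical(unname(can["y"]), "CC(=O)O")
  fx <- curationFlags(cs)$x
  expect_true(all(c("metal_disconnected", "salt_stripped", "neutralized")
                  %in% fx))
})

test_that("largest organic fragment survives fragment removal", {
  cs <- standardizeStructures(c(
    big = "c1ccccc1CCCC.CC",        # two organics: keep the larger
    org = "CCO.OS(=O)(=O)O"))       # organic + sulfate counter-fragment
  expect_identical(unname(canonicalSmiles(cs)["big"]), "CCCCc1ccccc1")
  expect_true("fragment_removed" %in% curationFlags(cs)$big)
  expect_identical(unname(canonicalSmiles(cs)["org"]), "CCO")
})

test_that("standardization is idempotent on a generated library", {
  lib <- small_library()
  cs <- standardizeStructures(lib$smiles[1:60])
  expect_true(all(isValid(cs)))
  again <- standardizeStructures(canonicalSmiles(cs), ids = compoundIds(cs))
  expect_identical(canonicalSmiles(again), canonicalSmiles(cs))
  # a second standardization alters nothing, so no flags are raised
  expect_true(all(lengths(curationFlags(again)) == 0L))
})

test_that("deduplication keeps one record per structure with the smallest id", {
  cs <- standardizeStructures(c(b2 = "OCC", a1 = "CCO", c3 = "CCN"))
  dd <- deduplicateCompounds(cs)
  expect_identical(compoundIds(dd), c("a1", "c3"))
  expect_identical(deduplicateCompounds(dd), dd)
  # tautomer spellings that normalize to one canonical form collapse too;
  # the expectation is derived from the standardizer itself
  t2 <- standardizeStructures(c(u = "CC(O)=CC", v = "CC=C(O)C"))
  if (length(unique(canonicalSmiles(t2))) == 1L)
    expect_length(deduplicateCompounds(t2), 1L)
  # empty input is the identity
  empty <- standardizeStructures(character(0), ids = character(0))
  expect_length(deduplicateCompounds(empty), 0L)
  # invalid entries are a contract violation
  bad <- standardizeStructures(c(q = "C1CC", r = "CCO"))
  expect_error(deduplicateCompounds(bad), "invalid")
})

test_that("feature vectors have the scheme's fixed length", {
  cs <- standardizeStructures(c(a = "CCO", b = "c1ccccc1O",
                                f = "CCS(=O)(=O)N"))
  fp <- featurizeCompounds(cs, "circular_fingerprint")
  expect_identical(dim(fp), c(3L, 5120L))
  expect_true(all(fp %in% c(0, 1)))
  keys <- featurizeCompounds(cs, "structural_keys")
  expect_identical(ncol(keys), 166L)
  de <- featurizeCompounds(cs, "descriptors")
  expect_identical(ncol(de), 200L)
  expect_true(all(is.finite(de)))
  expect_identical(rownames(de), c("a", "b", "f"))
  # the sulfonamide is visible to the descriptor panel
  expect_identical(unname(de["f", "grp_sulfonamide"]), 1)
})

test_that("featurization is canonical: spelling and atom order do not matter", {
  sp <- standardizeStructures(c(x = "OCC", y = "C(O)C", z = "CCO"))
  for (scheme in c("circular_fingerprint", "structural_keys", "descriptors")) {
    m <- featurizeCompounds(sp, scheme)
    expect_identical(unname(m["x", ]), unname(m["y", ]))
    expect_identical(unname(m["x", ]), unname(m["z", ]))
  }
  perm <- standardizeStructures(c(p = "c1ccc(cc1)S(=O)(=O)N",
                                  q = "NS(=O)(=O)c1ccccc1"))
  fp <- featurizeCompounds(perm, "circular_fingerprint")
  expect_identical(unname(fp["p", ]), unname(fp["q", ]))
})

test_that("fingerprint bit count is bounded by the number of atom environments", {
  lib <- small_library()
  cs <- standardizeStructures(lib$smiles[1:25])
  fp <- featurizeCompounds(cs, "circular_fingerprint")
  de <- featurizeCompounds(cs, "descriptors")
  # one environment per atom and radius (0, 1, 2)
  expect_true(all(rowSums(fp) <= 3 * de[, "n_heavy"]))
  expect_true(all(rowSums(fp) >= 1))
})

test_that("featurizing an invalid compound names the offender", {
  cs <- standardizeStructures(c(ok = "CCO", broken = "C1CC"))
  expect_error(featurizeCompounds(cs, "descriptors"), "broken")
})

test_that("curation report and feature matrix round-trip through files", {
  cs <- standardizeStructures(c(a = "CCO.Cl", b = "C1CC"))
  f <- tempfile(fileext = ".tsv")
  writeCurationReport(cs, f)
  rep <- utils::read.table(f, header = TRUE, sep = "\t", fill = TRUE)
  expect_identical(nrow(rep), 2L)
  expect_identical(rep$valid, c(TRUE, FALSE))
  m <- featurizeCompounds(cs["a"], "descriptors")
  fm <- tempfile(fileext = ".tsv")
  writeFeatureMatrix(m, fm)
  back <- utils::read.table(fm, header = TRUE, sep = "\t", check.names = FALSE)
  expect_identical(colnames(back)[-1L], colnames(m))
  expect_equal(unlist(back[1, -1L], use.names = FALSE), unname(m[1, ]))
})
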