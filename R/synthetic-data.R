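# Seeded generators for (a) an imbalanced compound library whose activity
# is a deterministic function of a planted substructure, optionally
# corrupted by label noise, and (b) a cohort metabolome with missingness,
# skewed abundances, correlated metabolite blocks and a log-scale outcome
# driven by a few planted metabolites. Every pipeline stage can be
# exercised with these without any external download.

# scaffold templates: @k@ markers are substitution slots; type "b" slots
# are wrapped in parentheses when filled, type "t" slots are appended raw
.scaffolds <- list(
  list(tmpl = "c1cc@1@cc@2@c1@3@",      type = c("b", "b", "t")),
  list(tmpl = "c1ccc@1@cc1CC@2@@3@",    type = c("b", "b", "t")),
  list(tmpl = "C1CCC@1@CC1@2@",         type = c("b", "t")),
  list(tmpl = "c1ccnc@1@c1@2@",         type = c("b", "t")),
  list(tmpl = "c1ccc2ccccc2c1@1@",      type = "t"),
  list(tmpl = "c1ccoc1@1@",             type = "t"),
  list(tmpl = "c1ccsc1@1@",             type = "t"),
  list(tmpl = "CC@1@CC@2@@3@",          type = c("b", "b", "t")),
  list(tmpl = "C1CCN@1@CC1@2@",         type = c("b", "t")),
  list(tmpl = "c1cnc@1@nc1@2@",         type = c("b", "t")),
  list(tmpl = "C1=CC@1@CCC1@2@",        type = c("b", "t")),
  list(tmpl = "c1ccc@1@c@2@c1@3@",      type = c("b", "b", "t")),
  list(tmpl = "OCC@1@C@2@",             type = c("b", "t")),
  list(tmpl = "c1ccc(CC@1@@2@)cc1",     type = c("b", "t")),
  list(tmpl = "C1CCOC1@1@",             type = "t"),
  list(tmpl = "CC(C)@1@C@2@",           type = c("b", "t")),
  list(tmpl = "c1ccc@1@cc1O@2@",        type = c("b", "t")),
  list(tmpl = "C@1@C@2@C@3@",           type = c("b", "b", "t")),
  list(tmpl = "C1CC1@1@",               type = "t"),
  list(tmpl = "c1ccc@1@c(O)c1@2@",      type = c("b", "t")))

.inactive_fragments <- c(
  "C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC", "N(C)C",
  "F", "Cl", "Br", "C#N", "C(=O)O", "C(=O)OC", "C(=O)N", "C(=O)NC",
  "CO", "CCO", "C=C", "CC=C", "C(F)(F)F", "OC(=O)C")

.active_fragments <- c(
  "S(=O)(=O)N", "S(=O)(=O)NC", "CS(=O)(=O)N", "CCS(=O)(=O)N",
  "S(=O)(=O)N(C)C", "NS(C)(=O)=O")

.fill_scaffold <- function(scaffold, frags) {
  s <- scaffold$tmpl
  for (k in seq_along(scaffold$type)) {
    f <- frags[k]
    rep <- if (!nzchar(f)) "" else if (scaffold$type[k] == "b")
      paste0("(", f, ")") else f
    s <- sub(paste0("@", k, "@"), rep, s, fixed = TRUE)
  }
  s
}

.random_compound <- function(active) {
  sc <- .scaffolds[[sample.int(length(.scaffolds), 1L)]]
  k <- length(sc$type)
  frags <- sample(c(.inactive_fragments, ""), k, replace = TRUE)
  if (active) {
    slot <- sample.int(k, 1L)
    frags[slot] <- sample(.active_fragments, 1L)
  }
  .fill_scaffold(sc, frags)
}

#' Generate a synthetic compound library with a planted activity rule
#'
#' Assembles valid SMILES by combinatorial scaffold decoration. A compound
#' is active if and only if it carries the planted substructure (a primary
#' or secondary sulfonamide by default); labels are then flipped with
#' probability `labelNoise`. The positive fraction is met exactly by
#' construction (generation is rejection-adjusted to unique canonical
#' structures) and the output is fully determined by the seed.
#'
#' @param nCompounds library size (default 2000).
#' @param positiveFraction fraction of active compounds, in (0, 1)
#'   (default 0.10).
#' @param plantedSubstructure SMARTS pattern defining activity (default
#'   `"S(=O)(=O)N"`); used by callers as the matching oracle.
#' @param labelNoise label flip probability in [0, 0.5) (default 0).
#' @param seed integer seed.
#' @param endpoint endpoint name written into the assay records (default
#'   `"NR-AR"`).
#' @return list with `smiles` (named character vector of raw SMILES),
#'   `records` (long-format data.frame `compound_id`, `endpoint`, `label`)
#'   and `truth` (the noise-free construction labels).
#' @export
syntheticLibrary <- function(nCompounds = 2000L, positiveFraction = 0.10,
                             plantedSubstructure = "S(=O)(=O)N",
                             labelNoise = 0, seed = 1L,
                             endpoint = "NR-AR") {
  stopifnot(positiveFraction > 0, positiveFraction < 1,
            labelNoise >= 0, labelNoise < 0.5, nCompounds >= 10L)
  n_pos <- round(nCompounds * positiveFraction)
  n_neg <- nCompounds - n_pos
  if (n_pos < 1L || n_neg < 1L)
    stop("positive fraction ", positiveFraction,
         " is infeasible for ", nCompounds, " compounds")
  set.seed(childSeed(seed, "library"))
  gen_unique <- function(n, active, avoid = character(0)) {
    out <- character(0)
    for (iter in 1:60) {
      if (length(out) >= n) break
      raw <- vapply(seq_len(2L * (n - length(out)) + 10L),
                    function(i) .random_compound(active), "")
      can <- .ob_canonical(raw)
      ok <- !is.na(can) & !duplicated(can) &
        !(can %in% c(avoid, names(out)))
      out <- c(out, stats::setNames(raw[ok], can[ok]))
    }
    if (length(out) < n)
      stop("could not assemble ", n, " unique ",
           if (active) "active" else "inactive", " structures")
    out[seq_len(n)]
  }
  act <- gen_unique(n_pos, TRUE)
  inact <- gen_unique(n_neg, FALSE, avoid = names(act))
  raw <- c(act, inact)
  truth <- c(rep(1L, n_pos), rep(0L, n_neg))
  ord <- sample(nCompounds)
  raw <- raw[ord]; truth <- truth[ord]
  ids <- sprintf("SYN%05d", seq_len(nCompounds))
  labels <- truth
  if (labelNoise > 0) {
    flip <- stats::runif(nCompounds) < labelNoise
    labels[flip] <- 1L - labels[flip]
  }
  list(smiles = stats::setNames(unname(raw), ids),
       records = data.frame(compound_id = ids, endpoint = endpoint,
                            label = labels, stringsAsFactors = FALSE),
       truth = stats::setNames(truth, ids))
}

#' Generate synthetic metabolite structures
#'
#' The first `nBioactive` metabolites carry the planted substructure (so a
#' model trained on the planted rule predicts them active); the rest do
#' not. A trailing fraction is left unannotated (`NA`) to exercise the
#' annotation bookkeeping.
#'
#' @param nMetabolites number of metabolites.
#' @param nBioactive number of substructure-bearing metabolites.
#' @param unannotatedFraction fraction of metabolites (taken from the end)
#'   without a SMILES annotation (default 0.1).
#' @param seed integer seed.
#' @return named character vector of raw SMILES (names `met_01`, ...).
#' @export
syntheticMetaboliteStructures <- function(nMetabolites = 60L,
                                          nBioactive = 12L,
                                          unannotatedFraction = 0.1,
                                          seed = 1L) {
  stopifnot(nBioactive <= nMetabolites)
  set.seed(childSeed(seed, "metabolites"))
  gen <- function(n, active) {
    out <- character(0)
    for (iter in 1:60) {
      if (length(out) >= n) break
      raw <- vapply(seq_len(2L * n + 10L),
                    function(i) .random_compound(active), "")
      can <- .ob_canonical(raw)
      ok <- which(!is.na(can))
      new <- stats::setNames(raw[ok], can[ok])
      new <- new[!duplicated(names(new)) & !(names(new) %in% names(out))]
      out <- c(out, new)
    }
    out[seq_len(n)]
  }
  act <- gen(nBioactive, TRUE)
  inact <- gen(nMetabolites - nBioactive, FALSE)
  # spread the substructure-bearing metabolites across the panel so that
  # they land in different correlation blocks of the cohort generator
  pos_act <- unique(round(seq(1L, nMetabolites, length.out = nBioactive)))
  while (length(pos_act) < nBioactive)
    pos_act <- sort(union(pos_act, sample.int(nMetabolites, 1L)))
  smi <- character(nMetabolites)
  smi[pos_act] <- act
  smi[-pos_act] <- inact
  names(smi) <- sprintf("met_%02d", seq_len(nMetabolites))
  n_un <- floor(unannotatedFraction * nMetabolites)
  if (n_un > 0) {
    unann <- setdiff(seq_len(nMetabolites), pos_act)
    smi[utils::tail(unann, n_un)] <- NA_character_
  }
  attr(smi, "bioactive") <- names(smi)[pos_act]
  smi
}

#' Generate a synthetic cohort metabolome with planted outcome effects
#'
#' Abundances are drawn log-normally within correlated metabolite blocks
#' (a shared per-block subject factor gives pairwise correlation
#' `blockCorrelation` on the latent scale). The outcome is
#' `exp(intercept + sum of effect * standardized latent abundance + noise)`
#' so that the association stage's log transform and median imputation are
#' exercised on the measurement scale. Missing abundance cells are set
#' completely at random at `missingRate` (or left-censored below the
#' per-metabolite `missingRate` quantile when `censoredMissingness` is
#' `TRUE`). Fully seed-deterministic.
#'
#' @param nSubjects,nMetabolites cohort dimensions (defaults 500 x 60).
#' @param missingRate fraction of missing abundance cells in [0, 1)
#'   (default 0.15).
#' @param blockCorrelation latent within-block correlation in [0, 1)
#'   (default 0.6; blocks of 6 metabolites).
#' @param plantedEffects named numeric vector of effects on the log-outcome
#'   scale per standardized latent abundance; names must be metabolite
#'   names (default three effects of 0.6, -0.6, 0.5 on the first three
#'   bioactive metabolites).
#' @param outcomeNoiseSd Gaussian noise s.d. on the log-outcome scale
#'   (default 0.5).
#' @param seed integer seed.
#' @param smiles optional metabolite structure annotation; defaults to
#'   [syntheticMetaboliteStructures()] with 12 bioactive metabolites.
#' @param censoredMissingness left-censored missingness instead of
#'   missing-completely-at-random.
#' @param outcomeMissingRate fraction of missing outcome values
#'   (default 0.05).
#' @return list with `panel` (a [MetabolitePanel]), `outcome` (named
#'   vector, `NA` for missing), `plantedEffects` and `latent` (the
#'   standardized latent abundance matrix used to build the outcome).
#' @export
syntheticCohort <- function(nSubjects = 500L, nMetabolites = 60L,
                            missingRate = 0.02, blockCorrelation = 0.6,
                            plantedEffects = NULL, outcomeNoiseSd = 0.5,
                            seed = 1L, smiles = NULL,
                            censoredMissingness = FALSE,
                            outcomeMissingRate = 0.05) {
  stopifnot(missingRate >= 0, missingRate < 1,
            blockCorrelation >= 0, blockCorrelation < 1)
  if (is.null(smiles))
    smiles <- syntheticMetaboliteStructures(nMetabolites, seed = seed)
  stopifnot(length(smiles) == nMetabolites)
  mets <- names(smiles)
  if (is.null(plantedEffects)) {
    bio <- attr(smiles, "bioactive")
    if (is.null(bio) || length(bio) < 5L) bio <- mets[1:5]
    # three effects on substructure-bearing metabolites in distinct
    # correlation blocks
    plantedEffects <- stats::setNames(c(0.6, -0.6, 0.5), bio[c(1L, 3L, 5L)])
  }
  if (!all(names(plantedEffects) %in% mets))
    stop("plantedEffects must name metabolites of the panel")
  set.seed(childSeed(seed, "cohort"))
  subjects <- sprintf("child_%03d", seq_len(nSubjects))
  block <- rep(seq_len(ceiling(nMetabolites / 6)), each = 6L)[seq_len(nMetabolites)]
  z <- matrix(0, nSubjects, nMetabolites, dimnames = list(subjects, mets))
  for (b in unique(block)) {
    members <- which(block == b)
    f <- stats::rnorm(nSubjects)
    for (j in members)
      z[, j] <- sqrt(blockCorrelation) * f +
        sqrt(1 - blockCorrelation) * stats::rnorm(nSubjects)
  }
  mu <- stats::runif(nMetabolites, log(1e4), log(1e6))
  sd_j <- stats::runif(nMetabolites, 0.4, 1.0)
  # planted metabolites emulate robustly quantified biomarkers: moderate
  # log-scale dispersion, so the planted signal is neither squashed by the
  # min-max scaling of a heavy upper tail nor removed by the low-variance
  # decile filter
  planted_idx <- mets %in% names(plantedEffects)
  sd_j[planted_idx] <- stats::runif(sum(planted_idx), 0.45, 0.65)
  x <- exp(sweep(sweep(z, 2L, sd_j, "*"), 2L, mu, "+"))
  log_y <- log(200) + as.numeric(z[, names(plantedEffects), drop = FALSE] %*%
                                   plantedEffects) +
    stats::rnorm(nSubjects, 0, outcomeNoiseSd)
  outcome <- stats::setNames(exp(log_y), subjects)
  if (missingRate > 0) {
    if (censoredMissingness) {
      for (j in seq_len(nMetabolites)) {
        thr <- stats::quantile(x[, j], missingRate)
        x[x[, j] < thr, j] <- NA
      }
    } else {
      miss <- matrix(stats::runif(nSubjects * nMetabolites) < missingRate,
                     nSubjects, nMetabolites)
      x[miss] <- NA
    }
  }
  if (outcomeMissingRate > 0)
    outcome[stats::runif(nSubjects) < outcomeMissingRate] <- NA
  list(panel = MetabolitePanel(x, smiles = smiles, subjectsAsRows = TRUE),
       outcome = outcome, plantedEffects = plantedEffects, latent = z)
}
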