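# From gated endpoint models to the concentration-weighted bioactive
# potential: per-metabolite activity probabilities, the p > 0.5 active
# mask, BiP = c * p per subject/metabolite/target, and
# sBiP = log10(sum over targets of BiP) per subject and metabolite.

#' Predict per-metabolite activity probabilities
#'
#' Applies a list of gated endpoint models to annotated metabolite
#' structures. Each model scores on its own feature scheme and selected
#' features; probabilities are the random forest's native class-1 vote
#' fraction (no recalibration). Metabolites whose structure fails
#' featurization are excluded with a message.
#'
#' @param models list of [EndpointModel] objects (typically the gated set).
#' @param compounds a [CompoundSet] of standardized metabolite structures,
#'   or a named character vector of canonical SMILES.
#' @return a metabolites x endpoints probability matrix (entries in [0, 1]).
#' @export
predictProbabilities <- function(models, compounds) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, is, logical(1), "EndpointModel")))
  if (is(compounds, "CompoundSet")) {
    ok <- compounds@data$valid
    if (any(!ok))
      message("excluding ", sum(!ok), " metabolite(s) without a valid structure")
    compounds <- compounds[which(ok)]
    smiles <- canonicalSmiles(compounds)
  } else {
    smiles <- compounds
    stopifnot(!is.null(names(smiles)))
    smiles <- smiles[!is.na(smiles)]
  }
  if (length(smiles) == 0L) stop("no scorable metabolite structures")
  schemes <- unique(vapply(models, featureScheme, ""))
  feats <- lapply(stats::setNames(schemes, schemes), function(s)
    featurizeCompounds(smiles, s))
  out <- matrix(NA_real_, length(smiles), length(models),
                dimnames = list(names(smiles),
                                vapply(models, function(m) m@endpoint, "")))
  for (k in seq_along(models)) {
    m <- models[[k]]
    X <- feats[[m@scheme]][, m@features, drop = FALSE]
    out[, k] <- .predict_prob(m@fit, X)
  }
  stopifnot(all(out >= 0 & out <= 1))
  out
}

#' Apply the bioactivity mask
#'
#' A metabolite is considered potentially bioactive when at least one
#' predicted probability strictly exceeds the threshold (default 0.5). The
#' per-metabolite set of active endpoints is attached as the
#' `"activeEndpoints"` attribute for reporting.
#'
#' @param probs metabolites x endpoints probability matrix from
#'   [predictProbabilities()].
#' @param threshold activity cut-off (strict inequality).
#' @return character vector of active metabolite names.
#' @export
activeMask <- function(probs, threshold = 0.5) {
  stopifnot(is.matrix(probs), all(probs >= 0 & probs <= 1))
  act <- probs > threshold
  mask <- rownames(probs)[rowSums(act) > 0]
  ep <- lapply(mask, function(m) colnames(probs)[act[m, ]])
  names(ep) <- mask
  structure(mask, activeEndpoints = ep)
}

#' Bioactive potential of one metabolite against one target
#'
#' BiP = c * p: the product of the metabolite's scaled relative peak area
#' and its predicted activity probability. Vectorized.
#'
#' @param c scaled abundance(s), non-negative.
#' @param p activity probability(ies) in [0, 1].
#' @return numeric BiP value(s).
#' @examples
#' computeBip(0.4, 0.8)  # 0.32
#' @export
computeBip <- function(c, p) {
  stopifnot(all(c >= 0), all(p >= 0 & p <= 1))
  c * p
}

#' Summed, log-transformed bioactive potential
#'
#' sBiP = log10(sum over the gated targets of BiP). A zero sum is floored
#' at `eps` before the log so the value stays finite (min-max-scaled
#' abundances can be exactly zero).
#'
#' @param bips non-negative BiP values over the gated endpoints.
#' @param eps flooring constant (default 1e-6).
#' @return the sBiP value.
#' @examples
#' computeSbip(c(0.05, 0.05))  # -1
#' @export
computeSbip <- function(bips, eps = 1e-6) {
  if (any(bips < 0)) stop("BiP summands must be non-negative")
  log10(max(sum(bips), eps))
}

#' sBiP table per subject and metabolite
#'
#' Computes BiP for every subject, masked metabolite and gated endpoint,
#' sums over endpoints and log-transforms, yielding one value per subject
#' and metabolite. The sum runs over all gated endpoints (sub-threshold
#' probabilities are not zeroed).
#'
#' Zero BiP sums arise for subjects whose scaled abundance is exactly zero
#' (the min-max minimum, typically the detection-limit-imputed cells).
#' Consistently with the 1/10-minimum detection-limit convention of the
#' abundance imputation, such sums are floored at one tenth of the
#' metabolite's smallest positive BiP sum, so censored subjects sit one
#' decade below the observed range instead of at an arbitrary absolute
#' level; `eps` is only the absolute fallback when a metabolite has no
#' positive sum at all. This per-metabolite relative floor also preserves
#' the scale equivariance of sBiP (abundances x k shift every value by
#' log10(k)), which an absolute floor would break.
#'
#' @param panel a cleaned [MetabolitePanel] (scaled abundances in [0, 1]).
#' @param probs probability matrix from [predictProbabilities()].
#' @param mask metabolite names from [activeMask()] (defaults to the mask
#'   at threshold 0.5).
#' @param eps absolute fallback floor (default 1e-6, as in
#'   [computeSbip()]).
#' @return subjects x metabolites matrix of sBiP values.
#' @export
sbipTable <- function(panel, probs, mask = activeMask(probs), eps = 1e-6) {
  stopifnot(is(panel, "MetabolitePanel"), is.matrix(probs))
  mask <- intersect(mask, rownames(panel))
  if (length(mask) == 0L) stop("no masked metabolites present in the panel")
  a <- SummarizedExperiment::assay(panel, "abundance")
  if (anyNA(a) || any(a < 0) || any(a > 1))
    stop("panel must be cleaned and scaled to [0, 1] before scoring")
  out <- matrix(NA_real_, ncol(a), length(mask),
                dimnames = list(colnames(a), mask))
  n_floor <- 0L
  for (m in mask) {
    bip <- outer(a[m, ], probs[m, ])         # subjects x endpoints
    s <- rowSums(bip)
    pos <- s[s > 0]
    floor_m <- if (length(pos)) max(min(pos) / 10, eps) else eps
    n_floor <- n_floor + sum(s < floor_m)
    out[, m] <- log10(pmax(s, floor_m))
  }
  if (n_floor > 0L)
    message(n_floor, " subject-metabolite sBiP value(s) floored at ", eps)
  out
}
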