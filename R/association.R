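# Association of the scored metabolome with the inflammation outcome:
# standardize and decorrelate the sBiP table, log-transform the outcome
# with median imputation, fit one joint ordinary-least-squares regression
# and report predictors passing the significance filter.

#' Standardize and decorrelate sBiP predictors
#'
#' Column-standardizes the subjects x metabolites sBiP table to zero mean
#' and unit variance, then prunes correlated columns with the same greedy
#' rule and threshold as the panel cleaning (see [pruneCorrelated()]).
#' Zero-variance columns are dropped with a warning.
#'
#' @param sbip subjects x metabolites matrix from [sbipTable()].
#' @param rMax correlation threshold (default 0.90).
#' @return the standardized, decorrelated predictor matrix.
#' @export
preparePredictors <- function(sbip, rMax = 0.90) {
  stopifnot(is.matrix(sbip), nrow(sbip) >= 2L, ncol(sbip) >= 1L)
  v <- apply(sbip, 2L, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance predictor(s): ",
            paste(head(colnames(sbip)[v == 0], 5L), collapse = ", "))
    sbip <- sbip[, v > 0, drop = FALSE]
  }
  if (ncol(sbip) == 0L) stop("no predictors left after variance check")
  z <- scale(sbip)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  keep <- .prune_correlated_names(z, rMax)
  z[, keep, drop = FALSE]
}

#' Prepare the outcome vector
#'
#' Missing outcome values are imputed with the median of the observed
#' values (on the raw measurement scale), then the vector is
#' log-transformed (natural log). Non-positive observed values are an
#' error.
#'
#' @param crp named numeric vector of per-subject outcome values (e.g.
#'   hs-CRP in ng/mL), `NA` for missing.
#' @return numeric vector of log outcome values, same order and names.
#' @export
prepareOutcome <- function(crp) {
  stopifnot(is.numeric(crp))
  obs <- crp[!is.na(crp)]
  if (length(obs) == 0L) stop("no observed outcome values")
  if (any(obs <= 0)) {
    bad <- names(crp)[!is.na(crp) & crp <= 0]
    if (is.null(bad) || !length(bad)) bad <- which(!is.na(crp) & crp <= 0)
    stop("non-positive outcome value(s) for: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  crp[is.na(crp)] <- stats::median(obs)
  log(crp)
}

#' Fit the metabolome-outcome association model
#'
#' One joint ordinary-least-squares regression of the log outcome on all
#' standardized sBiP predictors plus an intercept. Coefficients are per
#' unit of standardized sBiP on the log-outcome scale; p-values are the
#' two-sided OLS t-test p-values. The full coefficient table is returned;
#' rows with `p_value < alpha` (plus the intercept) form the significant
#' report in the `"significant"` attribute.
#'
#' @param X standardized predictor matrix from [preparePredictors()].
#' @param y log outcome vector from [prepareOutcome()].
#' @param alpha significance filter (default 0.001, chosen for a high
#'   number of predictors).
#' @return data.frame with columns `metabolite`, `coefficient`, `p_value`;
#'   the intercept is the last row.
#' @export
fitAssociation <- function(X, y, alpha = 0.001) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (nrow(X) <= ncol(X) + 1L)
    stop("need more subjects than predictors + 1 (",
         nrow(X), " vs ", ncol(X) + 1L, ")")
  q <- qr(cbind(Intercept = 1, X))
  if (q$rank < ncol(X) + 1L) {
    dropped <- colnames(cbind(Intercept = 1, X))[q$pivot[-seq_len(q$rank)]]
    stop("predictor matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)$coefficients
  coefs <- unname(sm[, 1L])
  pvals <- unname(sm[, 4L])
  tab <- data.frame(metabolite = c(colnames(X), "intercept"),
                    coefficient = c(coefs[-1L], coefs[1L]),
                    p_value = c(pvals[-1L], pvals[1L]),
                    stringsAsFactors = FALSE)
  sig <- tab[c(tab$p_value[-nrow(tab)] < alpha, TRUE), , drop = FALSE]
  structure(tab, significant = sig, alpha = alpha)
}
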