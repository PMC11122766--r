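# Cleaning and normalization of the subjects x metabolites relative peak
# area table, in the order: missingness filter -> 1/10-minimum imputation
# -> min-max scaling -> low-variance decile filter -> correlation pruning.
# Every step is a pure function of its input panel; subjects are never
# dropped and the metabolite set only shrinks.

.panel_assay <- function(panel) SummarizedExperiment::assay(panel, "abundance")

.panel_replace <- function(panel, values, keep_rows = NULL) {
  if (!is.null(keep_rows)) panel <- panel[keep_rows, ]
  SummarizedExperiment::assay(panel, "abundance") <- values
  panel
}

#' Filter metabolites by missingness
#'
#' Drops metabolites whose fraction of missing values is strictly greater
#' than `maxMissing` (default 0.33, i.e. metabolites observed in at least
#' 67% of subjects are kept; a missing fraction of exactly 0.33 is kept).
#'
#' @param panel a [MetabolitePanel].
#' @param maxMissing largest tolerated missing fraction.
#' @return the filtered [MetabolitePanel].
#' @export
filterMissingness <- function(panel, maxMissing = 0.33) {
  stopifnot(is(panel, "MetabolitePanel"))
  a <- .panel_assay(panel)
  frac <- rowMeans(is.na(a))
  panel[frac <= maxMissing, ]
}

#' Impute missing values with 1/10 of the per-metabolite minimum
#'
#' Each missing cell becomes one tenth of the smallest observed value of
#' that metabolite (a detection-limit assumption). A metabolite whose
#' observed minimum is zero is imputed with zero, with a warning.
#'
#' @param panel a [MetabolitePanel]; every metabolite needs at least one
#'   observed value (all-missing metabolites should have been filtered).
#' @return the imputed [MetabolitePanel] (no missing values).
#' @export
imputeMinFraction <- function(panel) {
  stopifnot(is(panel, "MetabolitePanel"))
  a <- .panel_assay(panel)
  if (!anyNA(a)) return(panel)
  nobs <- rowSums(!is.na(a))
  if (any(nobs == 0L))
    stop("all-missing metabolite(s): ",
         paste(head(rownames(a)[nobs == 0L], 5L), collapse = ", "),
         " (filter missingness first)")
  mins <- apply(a, 1L, min, na.rm = TRUE)
  zero_fill <- mins == 0 & rowSums(is.na(a)) > 0
  if (any(zero_fill))
    warning("observed minimum is zero for ", sum(zero_fill),
            " metabolite(s); missing cells imputed as 0")
  fill <- mins / 10
  idx <- which(is.na(a), arr.ind = TRUE)
  a[idx] <- fill[idx[, 1L]]
  .panel_replace(panel, a)
}

#' Min-max scale each metabolite to [0, 1]
#'
#' Per metabolite, x <- (x - min) / (max - min). Constant metabolites map
#' to 0.
#'
#' @param panel a complete (no missing values) [MetabolitePanel].
#' @return the scaled [MetabolitePanel].
#' @export
minMaxScale <- function(panel) {
  stopifnot(is(panel, "MetabolitePanel"))
  a <- .panel_assay(panel)
  if (anyNA(a)) stop("impute missing values before scaling")
  rmin <- apply(a, 1L, min)
  rmax <- apply(a, 1L, max)
  rng <- rmax - rmin
  scaled <- (a - rmin) / ifelse(rng > 0, rng, 1)
  scaled[rng == 0, ] <- 0
  .panel_replace(panel, scaled)
}

#' Drop the lowest decile of metabolites by variance
#'
#' Removes the `floor(quantile * m)` metabolites with the smallest
#' variance; ties are broken by metabolite name order.
#'
#' @param panel a scaled [MetabolitePanel].
#' @param quantile fraction of metabolites to remove (default 0.10).
#' @return the filtered [MetabolitePanel].
#' @export
dropLowVariance <- function(panel, quantile = 0.10) {
  stopifnot(is(panel, "MetabolitePanel"))
  a <- .panel_assay(panel)
  k <- floor(quantile * nrow(a))
  if (k < 1L) return(panel)
  v <- apply(a, 1L, stats::var)
  drop_idx <- order(v, rownames(a))[seq_len(k)]
  panel[-drop_idx, ]
}

# greedy correlation pruning shared by panel cleaning and the association
# stage: repeatedly take the most correlated pair above the threshold and
# drop the member with the larger mean absolute correlation to all other
# remaining columns (ties: the lexicographically larger name).
.prune_correlated_names <- function(m, r_max) {
  # m: observations x variables
  keep <- colnames(m)
  if (length(keep) < 2L) return(keep)
  cc <- abs(suppressWarnings(stats::cor(m)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 0
  while (TRUE) {
    mx <- max(cc)
    if (mx <= r_max) break
    hit <- which(cc == mx, arr.ind = TRUE)[1L, ]
    pair <- sort(rownames(cc)[hit])
    mean_r <- rowMeans(cc[pair, , drop = FALSE]) * ncol(cc) / max(1L, ncol(cc) - 1L)
    victim <- if (mean_r[1L] > mean_r[2L]) pair[1L]
              else if (mean_r[2L] > mean_r[1L]) pair[2L]
              else max(pair)
    keepcols <- setdiff(rownames(cc), victim)
    cc <- cc[keepcols, keepcols, drop = FALSE]
    if (length(keepcols) < 2L) break
  }
  keep[keep %in% rownames(cc)]
}

#' Prune highly correlated metabolites
#'
#' Greedy pruning of metabolite pairs with absolute Pearson correlation
#' strictly above `rMax` (default 0.90): the most correlated pair is
#' resolved first, dropping the member with the larger mean absolute
#' correlation to all remaining metabolites, until no pair exceeds the
#' threshold. Deterministic given the panel.
#'
#' @param panel a [MetabolitePanel] with at least 2 subjects.
#' @param rMax correlation threshold.
#' @return the pruned [MetabolitePanel].
#' @export
pruneCorrelated <- function(panel, rMax = 0.90) {
  stopifnot(is(panel, "MetabolitePanel"))
  a <- .panel_assay(panel)
  if (ncol(a) < 2L) stop("need at least 2 subjects to correlate")
  keep <- .prune_correlated_names(t(a), rMax)
  panel[keep, ]
}

#' Run the full metabolite preparation pipeline
#'
#' Missingness filter, 1/10-minimum imputation, min-max scaling, lowest
#' variance decile removal, correlation pruning - in that order. After the
#' pipeline the panel has no missing values, all values lie in [0, 1] and
#' no metabolite pair correlates above `rMax`.
#'
#' @param panel a [MetabolitePanel].
#' @param maxMissing,varQuantile,rMax step parameters (defaults 0.33, 0.10,
#'   0.90).
#' @return the cleaned [MetabolitePanel].
#' @export
prepareMetabolitePanel <- function(panel, maxMissing = 0.33,
                                   varQuantile = 0.10, rMax = 0.90) {
  panel <- filterMissingness(panel, maxMissing)
  panel <- imputeMinFraction(panel)
  panel <- minMaxScale(panel)
  panel <- dropLowVariance(panel, varQuantile)
  pruneCorrelated(panel, rMax)
}

#' Read a subjects x metabolites abundance table
#'
#' @param file delimited file: header row of metabolite names, first column
#'   subject identifiers; empty cells are missing.
#' @param annotations optional delimited file with columns
#'   `metabolite_name` and `smiles`.
#' @return a [MetabolitePanel].
#' @export
readMetabolitePanel <- function(file, annotations = NULL) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  d <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1L,
                         check.names = FALSE, na.strings = c("NA", ""))
  m <- as.matrix(d)
  smiles <- NULL
  if (!is.null(annotations)) {
    asep <- if (grepl("\\.csv$", annotations)) "," else "\t"
    ann <- utils::read.table(annotations, header = TRUE, sep = asep,
                             stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    stopifnot(all(c("metabolite_name", "smiles") %in% colnames(ann)))
    smiles <- stats::setNames(ann$smiles, ann$metabolite_name)
  }
  MetabolitePanel(m, smiles = smiles, subjectsAsRows = TRUE)
}

#' Write a panel as a subjects x metabolites table
#'
#' @param panel a [MetabolitePanel].
#' @param file output path (tab-separated, subject ids in the first
#'   column).
#' @export
writeMetabolitePanel <- function(panel, file) {
  a <- t(.panel_assay(panel))
  d <- data.frame(subject_id = rownames(a), a, check.names = FALSE)
  utils::write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
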