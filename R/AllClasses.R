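#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CompoundSet: curated chemical structures
#'
#' Holds the outcome of structure standardization for a batch of compounds:
#' the raw identifier and SMILES as supplied, the canonical SMILES after the
#' twelve-step standardization protocol, the set of curation steps that
#' altered each structure, and a validity flag. Invalid inputs are retained
#' with `valid = FALSE` and a diagnostic note so that batch curation never
#' aborts.
#'
#' @slot data a [S4Vectors::DataFrame] with columns `compound_id`,
#'   `raw_structure`, `canonical_structure`, `curation_flags`
#'   (";"-separated step names), `valid` (logical) and `note`.
#' @export
setClass("CompoundSet", representation(data = "DataFrame"))

setValidity("CompoundSet", function(object) {
  d <- object@data
  need <- c("compound_id", "raw_structure", "canonical_structure",
            "curation_flags", "valid", "note")
  if (!all(need %in% colnames(d)))
    return(paste("missing columns:", paste(setdiff(need, colnames(d)),
                                           collapse = ", ")))
  if (anyDuplicated(d$compound_id))
    return("compound_id values must be unique")
  if (any(d$valid & (is.na(d$canonical_structure) |
                     !nzchar(d$canonical_structure))))
    return("valid compounds must carry a canonical structure")
  TRUE
})

#' EndpointDataset: labeled compounds for one bioassay endpoint
#'
#' Aligns a deduplicated [CompoundSet] with binary activity labels for one
#' of the twelve screening endpoints, and keeps the imbalance bookkeeping
#' (number of positives over number of labeled compounds).
#'
#' @slot endpoint one of the twelve endpoint names (see [tox21Endpoints()]).
#' @slot compounds a [CompoundSet] of valid, deduplicated structures.
#' @slot labels integer vector of 0/1 labels aligned with `compounds`.
#' @export
setClass("EndpointDataset",
         representation(endpoint = "character", compounds = "CompoundSet",
                        labels = "integer"))

setValidity("EndpointDataset", function(object) {
  if (length(object@endpoint) != 1L)
    return("endpoint must be a single name")
  if (length(object@labels) != length(object@compounds))
    return("labels must align 1:1 with compounds")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  can <- object@compounds@data$canonical_structure
  if (anyDuplicated(can))
    return("duplicate canonical structures in an endpoint dataset")
  if (!all(object@compounds@data$valid))
    return("all compounds in an endpoint dataset must be valid")
  TRUE
})

#' TrainTestSplit: an 80/20 partition of an endpoint dataset
#'
#' @slot train,test [EndpointDataset] objects with disjoint compounds.
#' @slot seed the integer seed that produced the split.
#' @export
setClass("TrainTestSplit",
         representation(train = "EndpointDataset", test = "EndpointDataset",
                        seed = "integer"))

setValidity("TrainTestSplit", function(object) {
  tr <- object@train@compounds@data$canonical_structure
  te <- object@test@compounds@data$canonical_structure
  if (length(intersect(tr, te)))
    return("train and test sets overlap")
  if (!identical(object@train@endpoint, object@test@endpoint))
    return("train and test must target the same endpoint")
  TRUE
})

#' EndpointModel: a fitted per-endpoint bioactivity classifier
#'
#' Wraps a fitted random-forest classifier together with the feature scheme
#' it was trained on, the selected feature names, the winning
#' hyperparameters, its performance metrics (MCC / balanced accuracy on
#' train, cross-validation and test) and the seed that produced it.
#'
#' @slot endpoint endpoint name.
#' @slot scheme feature scheme (`"descriptors"`, `"circular_fingerprint"` or
#'   `"structural_keys"`).
#' @slot features ordered character vector of selected feature names.
#' @slot hyperparameters named list incl. the class-weighting mode.
#' @slot fit the fitted classifier (a `ranger` object).
#' @slot metrics one-row data.frame with columns `mcc_train`, `bacc_train`,
#'   `mcc_cv`, `mcc_test`, `bacc_test`, `n_features`.
#' @slot seed integer seed.
#' @export
setClass("EndpointModel",
         representation(endpoint = "character", scheme = "character",
                        features = "character", hyperparameters = "list",
                        fit = "ANY", metrics = "data.frame",
                        seed = "integer"))

setValidity("EndpointModel", function(object) {
  m <- object@metrics
  need <- c("mcc_train", "bacc_train", "mcc_cv", "mcc_test", "bacc_test",
            "n_features")
  if (nrow(m) != 1L || !all(need %in% colnames(m)))
    return("metrics must be a one-row table with the five metric columns and n_features")
  mccs <- unlist(m[c("mcc_train", "mcc_cv", "mcc_test")])
  if (any(!is.na(mccs) & (mccs < -1 | mccs > 1)))
    return("MCC values must lie in [-1, 1]")
  baccs <- unlist(m[c("bacc_train", "bacc_test")])
  if (any(!is.na(baccs) & (baccs < 0 | baccs > 1)))
    return("balanced accuracy must lie in [0, 1]")
  if (m$n_features < 1L) return("n_features must be >= 1")
  if (length(object@features) != m$n_features)
    return("n_features must equal the number of selected features")
  TRUE
})

#' MetabolitePanel: subjects x metabolites abundance matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with metabolites as rows
#' and subjects as columns. The single assay `"abundance"` holds relative
#' peak areas (non-negative; `NA` for missing). `rowData(x)$smiles` carries
#' the optional structure annotation per metabolite.
#'
#' @export
setClass("MetabolitePanel", contains = "SummarizedExperiment")

setValidity("MetabolitePanel", function(object) {
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("a MetabolitePanel needs an 'abundance' assay")
  a <- SummarizedExperiment::assay(object, "abundance")
  if (any(a < 0, na.rm = TRUE))
    return("abundances must be non-negative")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("metabolite (row) and subject (column) names are required")
  TRUE
})
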