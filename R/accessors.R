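#' Accessors for CompoundSet
#'
#' @param x a [CompoundSet].
#' @return `compoundIds`, `rawSmiles`, `canonicalSmiles`: character vectors;
#'   `curationFlags`: a named list of character vectors (step names that
#'   altered each structure); `isValid`: a logical vector.
#' @name CompoundSet-accessors
#' @aliases compoundIds rawSmiles canonicalSmiles curationFlags isValid
NULL

#' @rdname CompoundSet-accessors
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@data$compound_id)

#' @rdname CompoundSet-accessors
#' @export
setMethod("rawSmiles", "CompoundSet", function(x)
  stats::setNames(x@data$raw_structure, x@data$compound_id))

#' @rdname CompoundSet-accessors
#' @export
setMethod("canonicalSmiles", "CompoundSet", function(x)
  stats::setNames(x@data$canonical_structure, x@data$compound_id))

#' @rdname CompoundSet-accessors
#' @export
setMethod("curationFlags", "CompoundSet", function(x) {
  fl <- strsplit(x@data$curation_flags, ";", fixed = TRUE)
  fl <- lapply(fl, function(v) v[nzchar(v)])
  names(fl) <- x@data$compound_id
  fl
})

#' @rdname CompoundSet-accessors
#' @export
setMethod("isValid", "CompoundSet", function(x)
  stats::setNames(x@data$valid, x@data$compound_id))

#' @export
setMethod("length", "CompoundSet", function(x) nrow(x@data))

#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@data$compound_id)
  new("CompoundSet", data = x@data[i, , drop = FALSE])
})

#' @export
setMethod("show", "CompoundSet", function(object) {
  d <- object@data
  cat("CompoundSet with", nrow(d), "compounds (",
      sum(d$valid), "valid )\n")
  if (nrow(d)) {
    k <- head(seq_len(nrow(d)), 5L)
    for (i in k)
      cat(sprintf("  %s: %s%s\n", d$compound_id[i],
                  ifelse(d$valid[i], d$canonical_structure[i], "<invalid>"),
                  ifelse(nzchar(d$curation_flags[i]),
                         paste0(" [", d$curation_flags[i], "]"), "")))
    if (nrow(d) > 5L) cat("  ...\n")
  }
  invisible(object)
})

#' Accessors for EndpointDataset
#'
#' @param x an [EndpointDataset].
#' @return `endpointName`: the endpoint; `nPos`/`nTotal`: the imbalance
#'   bookkeeping counts; `labels01`: the integer label vector; `compounds`:
#'   the underlying [CompoundSet].
#' @name EndpointDataset-accessors
#' @aliases endpointName nPos nTotal labels01 compounds
NULL

#' @rdname EndpointDataset-accessors
#' @export
setMethod("endpointName", "EndpointDataset", function(x) x@endpoint)

#' @rdname EndpointDataset-accessors
#' @export
setMethod("nPos", "EndpointDataset", function(x) sum(x@labels == 1L))

#' @rdname EndpointDataset-accessors
#' @export
setMethod("nTotal", "EndpointDataset", function(x) length(x@labels))

#' @rdname EndpointDataset-accessors
#' @export
setMethod("labels01", "EndpointDataset", function(x)
  stats::setNames(x@labels, compoundIds(x@compounds)))

#' @rdname EndpointDataset-accessors
#' @export
setMethod("compounds", "EndpointDataset", function(x) x@compounds)

#' @export
setMethod("show", "EndpointDataset", function(object) {
  cat(sprintf("EndpointDataset %s: %d/%d positives (N(1)/N(0,1))\n",
              object@endpoint, nPos(object), nTotal(object)))
  invisible(object)
})

#' Accessors for TrainTestSplit
#'
#' @param x a [TrainTestSplit].
#' @return `trainSet`/`testSet`: the two [EndpointDataset] partitions.
#' @name TrainTestSplit-accessors
#' @aliases trainSet testSet
NULL

#' @rdname TrainTestSplit-accessors
#' @export
setMethod("trainSet", "TrainTestSplit", function(x) x@train)

#' @rdname TrainTestSplit-accessors
#' @export
setMethod("testSet", "TrainTestSplit", function(x) x@test)

#' @export
setMethod("show", "TrainTestSplit", function(object) {
  cat(sprintf("TrainTestSplit %s: train %d (%d pos) / test %d (%d pos), seed %d\n",
              object@train@endpoint, nTotal(object@train), nPos(object@train),
              nTotal(object@test), nPos(object@test), object@seed))
  invisible(object)
})

#' Accessors for EndpointModel
#'
#' @param x an [EndpointModel].
#' @return `modelMetrics`: one-row data.frame of MCC/BACC metrics;
#'   `selectedFeatures`: character vector; `featureScheme`: the scheme name.
#' @name EndpointModel-accessors
#' @aliases modelMetrics selectedFeatures featureScheme
NULL

#' @rdname EndpointModel-accessors
#' @export
setMethod("modelMetrics", "EndpointModel", function(x) x@metrics)

#' @rdname EndpointModel-accessors
#' @export
setMethod("selectedFeatures", "EndpointModel", function(x) x@features)

#' @rdname EndpointModel-accessors
#' @export
setMethod("featureScheme", "EndpointModel", function(x) x@scheme)

#' @export
setMethod("show", "EndpointModel", function(object) {
  m <- object@metrics
  cat(sprintf(paste0("EndpointModel %s (%s, %d features)\n",
                     "  MCC train %.2f | CV %.2f | test %.2f;",
                     " BACC train %.2f | test %.2f\n"),
              object@endpoint, object@scheme, m$n_features,
              m$mcc_train, m$mcc_cv, m$mcc_test, m$bacc_train, m$bacc_test))
  invisible(object)
})

#' Accessors for MetabolitePanel
#'
#' @param x a [MetabolitePanel].
#' @return `abundances`: the metabolites x subjects abundance matrix;
#'   `metaboliteSmiles`: named character vector of structure annotations
#'   (`NA` where a metabolite has no resolvable structure).
#' @name MetabolitePanel-accessors
#' @aliases abundances metaboliteSmiles
NULL

#' @rdname MetabolitePanel-accessors
#' @export
setMethod("abundances", "MetabolitePanel", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' @rdname MetabolitePanel-accessors
#' @export
setMethod("metaboliteSmiles", "MetabolitePanel", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  s <- if ("smiles" %in% colnames(rd)) rd$smiles else rep(NA_character_, nrow(x))
  stats::setNames(as.character(s), rownames(x))
})

#' Construct a MetabolitePanel
#'
#' @param values numeric matrix of relative peak areas, either
#'   subjects x metabolites (default orientation of delimited exports) or
#'   metabolites x subjects; set `subjectsAsRows` accordingly.
#' @param smiles optional named character vector mapping metabolite names to
#'   SMILES annotations.
#' @param subjectsAsRows `TRUE` when `values` has subjects as rows.
#' @return a [MetabolitePanel].
#' @examples
#' m <- matrix(runif(12), 4, 3,
#'             dimnames = list(paste0("s", 1:4), paste0("met", 1:3)))
#' MetabolitePanel(m)
#' @export
MetabolitePanel <- function(values, smiles = NULL, subjectsAsRows = TRUE) {
  stopifnot(is.matrix(values))
  if (subjectsAsRows) values <- t(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("met_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("subject_", seq_len(ncol(values)))
  ann <- rep(NA_character_, nrow(values))
  if (!is.null(smiles)) {
    idx <- match(rownames(values), names(smiles))
    ann <- as.character(smiles[idx])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values),
    rowData = S4Vectors::DataFrame(smiles = ann, row.names = rownames(values)))
  new("MetabolitePanel", se)
}

#' @export
setMethod("show", "MetabolitePanel", function(object) {
  a <- abundances(object)
  cat(sprintf("MetabolitePanel: %d metabolites x %d subjects (%.1f%% missing, %d annotated)\n",
              nrow(a), ncol(a), 100 * mean(is.na(a)),
              sum(!is.na(metaboliteSmiles(object)))))
  invisible(object)
})
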