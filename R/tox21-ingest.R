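# Assembly of per-endpoint labeled datasets from raw assay records and the
# stratified 80/20 train/test partition.

#' The twelve screening endpoints
#'
#' Seven nuclear-receptor (NR) and five stress-response (SR) bioactivity
#' endpoints from the public screening library used for QSAR training.
#'
#' @return character vector of the twelve endpoint names.
#' @export
tox21Endpoints <- function() {
  c("NR-AR", "NR-AR-LBD", "NR-ER", "NR-ER-LBD", "NR-Aromatase", "NR-AhR",
    "NR-PPAR-gamma", "SR-ARE", "SR-ATAD5", "SR-HSE", "SR-MMP", "SR-p53")
}

.check_endpoint <- function(endpoint) {
  if (!(is.character(endpoint) && length(endpoint) == 1L &&
        endpoint %in% tox21Endpoints()))
    stop("unknown endpoint '", endpoint, "'; valid endpoints are: ",
         paste(tox21Endpoints(), collapse = ", "))
  invisible(endpoint)
}

#' Read assay records in long format
#'
#' @param file delimited file with header columns `compound_id`, `endpoint`,
#'   `label` (0/1; empty or NA = missing).
#' @return data.frame of bioassay records.
#' @export
readBioassayLong <- function(file) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  stopifnot(all(c("compound_id", "endpoint", "label") %in% colnames(d)))
  d$label <- as.integer(d$label)
  d
}

#' Read a challenge-style SDF with per-endpoint label tags
#'
#' Each record's data block may carry one tag per endpoint (named exactly as
#' in [tox21Endpoints()]) with a 0/1 label; absent tags are missing labels.
#' The molecule title (or a `compound_id` tag) provides the identifier.
#'
#' @param file path to an SDF (V2000).
#' @return list with `smiles` (named character vector, raw SMILES by
#'   compound id) and `records` (long-format data.frame of labels).
#' @export
readBioassaySDF <- function(file) {
  sdfset <- ChemmineR::read.SDFset(file)
  n <- length(sdfset)
  ids <- character(n)
  smi <- character(n)
  recs <- list()
  for (i in seq_len(n)) {
    sdf <- sdfset[[i]]
    db <- ChemmineR::datablock(sdf)
    ids[i] <- if ("compound_id" %in% names(db)) db[["compound_id"]]
              else ChemmineR::sdfid(sdf)
    smi[i] <- tryCatch(
      as.character(ChemmineR::sdf2smiles(sdfset[i])),
      error = function(e) NA_character_)
    tags <- intersect(names(db), tox21Endpoints())
    if (length(tags))
      recs[[length(recs) + 1L]] <- data.frame(
        compound_id = ids[i], endpoint = tags,
        label = suppressWarnings(as.integer(db[tags])),
        stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs)
             else data.frame(compound_id = character(0),
                             endpoint = character(0), label = integer(0))
  list(smiles = stats::setNames(smi, ids), records = records)
}

#' Assemble one endpoint dataset
#'
#' Joins assay records for one endpoint with curated structures, dropping
#' records with missing labels or invalid/unknown structures. Structural
#' duplicates (identical canonical SMILES) with agreeing labels collapse to
#' one compound; duplicates with conflicting labels are dropped entirely
#' (the conservative resolution, logged via a message).
#'
#' @param records data.frame with columns `compound_id`, `endpoint`, `label`.
#' @param curated a [CompoundSet] of standardized structures (deduplication
#'   by structure happens here, after label reconciliation).
#' @param endpoint one of [tox21Endpoints()].
#' @return an [EndpointDataset]; `nPos()`/`nTotal()` give the imbalance
#'   bookkeeping.
#' @export
assembleEndpoint <- function(records, curated, endpoint) {
  .check_endpoint(endpoint)
  stopifnot(is(curated, "CompoundSet"),
            all(c("compound_id", "endpoint", "label") %in% colnames(records)))
  r <- records[records$endpoint == endpoint & !is.na(records$label), ,
               drop = FALSE]
  r <- r[r$label %in% c(0L, 1L), , drop = FALSE]
  d <- curated@data
  idx <- match(r$compound_id, d$compound_id)
  keep <- rep(FALSE, length(idx))
  keep[!is.na(idx)] <- d$valid[idx[!is.na(idx)]]
  r <- r[keep, , drop = FALSE]
  idx <- idx[keep]
  can <- d$canonical_structure[idx]
  # reconcile labels per canonical structure
  lab_by_can <- split(as.integer(r$label), can)
  id_by_can <- split(r$compound_id, can)
  n_lab <- vapply(lab_by_can, function(v) length(unique(v)), 0L)
  conflicted <- names(lab_by_can)[n_lab > 1L]
  if (length(conflicted))
    message(endpoint, ": dropped ", length(conflicted),
            " structure(s) with conflicting duplicate labels")
  ok <- names(lab_by_can)[n_lab == 1L]
  labels <- vapply(lab_by_can[ok], function(v) v[[1L]], 0L)
  surv_id <- vapply(id_by_can[ok], function(v) sort(v)[[1L]], "")
  ord <- order(surv_id)
  surv_id <- surv_id[ord]
  labels <- unname(labels[ord])
  cs <- curated[match(surv_id, d$compound_id)]
  new("EndpointDataset", endpoint = endpoint, compounds = cs,
      labels = as.integer(labels))
}

#' Split an endpoint dataset into train and test
#'
#' Random split into train/test fractions, stratified by label so that an
#' endpoint with few percent positives cannot end up with a degenerate test
#' set. Identical seeds give identical splits.
#'
#' @param ds an [EndpointDataset] with at least 5 compounds and both classes.
#' @param fraction train fraction (default 0.8); per class,
#'   `floor(fraction * n_class)` compounds go to train.
#' @param seed integer seed.
#' @return a [TrainTestSplit].
#' @export
splitTrainTest <- function(ds, fraction = 0.8, seed = 1L) {
  stopifnot(is(ds, "EndpointDataset"), fraction > 0, fraction < 1)
  n <- nTotal(ds)
  if (n < 5L)
    stop("dataset too small to split (n = ", n, ", need >= 5)")
  if (nPos(ds) == 0L || nPos(ds) == n)
    stop("both classes must be present to split")
  set.seed(as.integer(seed))
  tr_idx <- integer(0)
  for (cl in c(0L, 1L)) {
    members <- which(ds@labels == cl)
    k <- floor(fraction * length(members))
    if (k < 1L)
      stop("a ", fraction, " split would leave class ", cl,
           " empty in train; use more data or a different fraction")
    tr_idx <- c(tr_idx, sort(sample(members, k)))
  }
  tr_idx <- sort(tr_idx)
  te_idx <- setdiff(seq_len(n), tr_idx)
  if (length(te_idx) == 0L)
    stop("split left an empty test set")
  sub <- function(i) new("EndpointDataset", endpoint = ds@endpoint,
                         compounds = ds@compounds[i],
                         labels = ds@labels[i])
  new("TrainTestSplit", train = sub(tr_idx), test = sub(te_idx),
      seed = as.integer(seed))
}

#' Per-endpoint counts report
#'
#' @param datasets list of [EndpointDataset] objects.
#' @return data.frame with columns `endpoint`, `n_pos`, `n_total` and the
#'   formatted imbalance ratio `ratio` ("n_pos/n_total").
#' @export
endpointCounts <- function(datasets) {
  do.call(rbind, lapply(datasets, function(d)
    data.frame(endpoint = endpointName(d), n_pos = nPos(d),
               n_total = nTotal(d),
               ratio = sprintf("%d/%d", nPos(d), nTotal(d)),
               stringsAsFactors = FALSE)))
}
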