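# Twelve-step structure standardization. The protocol, applied in order:
#   (1) removal of explicit hydrogens, (2) dearomatization, (3) conversion
#   of pi-metal bonds, (4) disconnection of metal atoms, (5) stripping of
#   salts, (6) fragment removal, (7) transformation of diazonium groups,
#   (8) neutralization, (9) wedge clean, (10) mesomer/tautomer
#   normalization, (11) aromatization, (12) 2D clean.
# Steps 1, 2, 8, 10, 11 and 12 are delegated to OpenBabel (-d, Kekule
# SMILES, --neutralize, obtautomer's canonical tautomer, canonical aromatic
# SMILES). Steps 3-7 are applied in-package on the SMILES fragments. Steps 9
# and 12 are structural no-ops for SMILES input (they act on depictions) and
# are recorded as absent flags.

# Counter-ions and solvents dropped by salt stripping, written as the raw
# forms whose OpenBabel canonical SMILES are matched against fragments.
.salt_fragments_raw <- c(
  "Cl", "Br", "I", "F", "O", "N",
  "[Cl-]", "[Br-]", "[I-]", "[F-]", "[OH-]",
  "[Na+]", "[K+]", "[Li+]", "[NH4+]", "[Ca+2]", "[Mg+2]", "[Zn+2]",
  "[Na]", "[K]", "[Li]",
  "O=[N+]([O-])O", "OS(=O)(=O)O", "OS(=O)O", "OP(=O)(O)O",
  "CS(=O)(=O)O", "Cc1ccc(S(=O)(=O)O)cc1",
  "CC(=O)O", "OC(=O)C(F)(F)F", "OC(=O)C=CC(=O)O", "OC(=O)C(=O)O",
  "C(=O)(O)O")

.salt_dictionary <- function() {
  if (is.null(.metabobip_cache$salt_dict)) {
    can <- .ob_canonical(.salt_fragments_raw)
    .metabobip_cache$salt_dict <- unique(can[!is.na(can)])
  }
  .metabobip_cache$salt_dict
}

.metal_regex <- "\\[(Li|Na|K|Rb|Cs|Mg|Ca|Sr|Ba|Al|Zn|Fe|Cu|Mn|Ni|Co|Ag|Hg|Pb|Sn|Pt|Pd|Cr|Ti)[0-9+]*\\]"

# Disconnect covalently written alkali/alkaline-earth-oxygen(sulfur) bonds,
# e.g. carboxylates drawn as CC(=O)O[Na]. Charges are separated so that
# salt stripping can drop the metal counter-ion afterwards.
.disconnect_metals <- function(s) {
  pats <- list(
    c("O\\[(Na|K|Li)\\]", "[O-].[\\1+]"),
    c("\\[(Na|K|Li)\\]O", "[\\1+].[O-]"),
    c("S\\[(Na|K|Li)\\]", "[S-].[\\1+]"),
    c("\\[(Na|K|Li)\\]S", "[\\1+].[S-]"))
  changed <- FALSE
  for (p in pats) {
    s2 <- gsub(p[1L], p[2L], s)
    if (!identical(s2, s)) changed <- TRUE
    s <- s2
  }
  list(smiles = s, changed = changed)
}

# Normalize terminal diazo spellings R-N=N / R-N=[N] to the diazonium
# cation spelling R-[N+]#N.
.transform_diazonium <- function(s) {
  pats <- c("N=\\[N\\]\\)", "N=\\[N\\]$", "N=N\\)", "N=N$")
  reps <- c("[N+]#N)", "[N+]#N", "[N+]#N)", "[N+]#N")
  changed <- FALSE
  for (k in seq_along(pats)) {
    s2 <- sub(pats[k], reps[k], s)
    if (!identical(s2, s)) changed <- TRUE
    s <- s2
  }
  list(smiles = s, changed = changed)
}

.parse_formula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1L]]
  toks <- regmatches(f, list(m))[[1L]]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  stats::setNames(ct, el)
}

# Heavy atom count and molecular weight per fragment (used for the
# largest-organic-fragment rule; ties broken by MW then lexicographically).
.fragment_info <- function(frags) {
  mols <- .ob_parse(frags)
  out <- data.frame(smiles = frags, heavy = 0L, mw = 0, organic = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(mols)) {
    if (is.null(mols[[i]])) next
    p <- tryCatch(ChemmineOB::prop_OB(mols[[i]]), error = function(e) NULL)
    if (is.null(p)) next
    counts <- .parse_formula(p$formula)
    out$heavy[i] <- sum(counts[setdiff(names(counts), "H")])
    out$mw[i] <- p$MW
    out$organic[i] <- "C" %in% names(counts)
  }
  out
}

.pick_largest_fragment <- function(frags) {
  info <- .fragment_info(frags)
  pool <- if (any(info$organic)) info[info$organic, , drop = FALSE] else info
  ord <- order(-pool$heavy, -pool$mw, pool$smiles)
  pool$smiles[ord[1L]]
}

#' Standardize raw chemical structures
#'
#' Applies the twelve-step standardization protocol to a batch of raw SMILES
#' strings and returns a [CompoundSet] with canonical SMILES, per-compound
#' curation flags and validity. Unparseable inputs yield `valid = FALSE`
#' with a diagnostic note; the batch never aborts. Standardization is
#' idempotent: re-standardizing a canonical structure returns it unchanged.
#'
#' @param smiles character vector of raw SMILES.
#' @param ids compound identifiers (defaults to names of `smiles`, else
#'   `cpd_1`, `cpd_2`, ...).
#' @return a [CompoundSet].
#' @examples
#' \donttest{
#' cs <- standardizeStructures(c(a = "CCO.Cl", b = "C1=CC=CC=C1"))
#' canonicalSmiles(cs)
#' curationFlags(cs)
#' }
#' @export
standardizeStructures <- function(smiles, ids = names(smiles)) {
  stopifnot(is.character(smiles))
  if (is.null(ids)) ids <- paste0("cpd_", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  n <- length(smiles)
  flags <- vector("list", n)
  note <- character(n)
  valid <- rep(TRUE, n)

  bad_input <- is.na(smiles) | !nzchar(trimws(smiles))
  note[bad_input] <- "empty input"
  valid[bad_input] <- FALSE

  # steps 1-2: drop explicit hydrogens, emit Kekule (dearomatized) SMILES
  cur <- rep(NA_character_, n)
  cur[!bad_input] <- .ob_convert(smiles[!bad_input], c("-d", "-xk"),
                                 out_format = "smi")
  failed <- valid & is.na(cur)
  note[failed] <- "parse failure"
  valid[failed] <- FALSE
  had_h <- grepl("\\[[0-9]*H[0-9]*\\]", smiles) & valid
  for (i in which(had_h)) flags[[i]] <- c(flags[[i]], "hydrogens_removed")

  # steps 3-4: pi-metal conversion / metal disconnection
  idx <- which(valid & grepl(.metal_regex, cur))
  for (i in idx) {
    r <- .disconnect_metals(cur[i])
    if (r$changed) {
      cur[i] <- r$smiles
      flags[[i]] <- c(flags[[i]], "metal_disconnected")
    }
  }

  # steps 5-6: salt stripping, then largest-organic-fragment removal
  multi <- which(valid & grepl(".", cur, fixed = TRUE))
  if (length(multi)) {
    frag_list <- strsplit(cur[multi], ".", fixed = TRUE)
    all_frags <- unique(unlist(frag_list))
    can_frags <- stats::setNames(.ob_canonical(all_frags), all_frags)
    dict <- .salt_dictionary()
    for (k in seq_along(multi)) {
      i <- multi[k]
      fr <- frag_list[[k]]
      fr_can <- unname(can_frags[fr])
      is_salt <- !is.na(fr_can) & fr_can %in% dict
      keep <- fr[!is_salt]
      if (length(keep) < length(fr) && length(keep) >= 1L) {
        flags[[i]] <- c(flags[[i]], "salt_stripped")
        fr <- keep
      } else if (length(keep) == 0L) {
        # nothing but dictionary fragments: keep the largest one
        flags[[i]] <- c(flags[[i]], "salt_stripped")
        fr <- .pick_largest_fragment(fr)
      }
      if (length(fr) > 1L) {
        fr <- .pick_largest_fragment(fr)
        flags[[i]] <- c(flags[[i]], "fragment_removed")
      }
      cur[i] <- fr
    }
  }

  # step 7: diazonium transformation
  idx <- which(valid & grepl("N=N$|N=N\\)|N=\\[N\\]", cur))
  for (i in idx) {
    r <- .transform_diazonium(cur[i])
    if (r$changed) {
      cur[i] <- r$smiles
      flags[[i]] <- c(flags[[i]], "diazonium_transformed")
    }
  }

  # step 8: neutralization (canonical output for comparison)
  ok <- which(valid)
  pre <- rep(NA_character_, n)
  pre[ok] <- .ob_canonical(cur[ok])
  neu <- rep(NA_character_, n)
  neu[ok] <- .ob_convert(cur[ok], "--neutralize")
  failed <- valid & is.na(neu)
  note[failed] <- "neutralization failure"
  valid[failed] <- FALSE
  for (i in which(valid)) {
    if (!is.na(pre[i]) && !identical(neu[i], pre[i]))
      flags[[i]] <- c(flags[[i]], "neutralized")
  }
  cur <- neu

  # step 9 (wedge clean): no 2D wedges exist in SMILES input; no-op.

  # step 10: mesomer/tautomer normalization (canonical tautomer)
  ok <- which(valid)
  tau <- rep(NA_character_, n)
  tau[ok] <- .ob_convert(cur[ok], "-c", tool = "obtautomer")
  # molecules the tautomer tool cannot process keep their current form
  tau[is.na(tau) & valid] <- cur[is.na(tau) & valid]

  # steps 11-12: aromatization + cleanup via final canonical SMILES
  fin <- rep(NA_character_, n)
  fin[ok] <- .ob_canonical(tau[ok])
  failed <- valid & is.na(fin)
  note[failed] <- "canonicalization failure"
  valid[failed] <- FALSE
  for (i in which(valid)) {
    if (!identical(fin[i], cur[i]))
      flags[[i]] <- c(flags[[i]], "tautomer_normalized")
  }

  fin[!valid] <- NA_character_
  flag_str <- vapply(flags, function(v) paste(unique(v), collapse = ";"), "")
  flag_str[!valid] <- ""
  new("CompoundSet", data = S4Vectors::DataFrame(
    compound_id = as.character(ids),
    raw_structure = as.character(smiles),
    canonical_structure = fin,
    curation_flags = flag_str,
    valid = valid,
    note = note))
}

#' Deduplicate standardized compounds
#'
#' Keeps at most one record per compound identifier and per canonical
#' structure. When several identifiers share one canonical structure, the
#' lexicographically smallest identifier survives. Output is sorted by
#' compound identifier. Label conflicts between structural duplicates are
#' not resolved here but during endpoint assembly (see
#' [assembleEndpoint()]).
#'
#' @param x a [CompoundSet] whose entries are all valid.
#' @return a [CompoundSet].
#' @export
deduplicateCompounds <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  d <- x@data
  if (nrow(d) == 0L) return(x)
  if (!all(d$valid))
    stop("deduplicateCompounds expects valid compounds only; ",
         sum(!d$valid), " invalid entries present")
  d <- d[order(d$compound_id), , drop = FALSE]
  d <- d[!duplicated(d$canonical_structure), , drop = FALSE]
  new("CompoundSet", data = d)
}

#' Read a two-column compound table (id, SMILES)
#'
#' @param file path to a delimited file with columns `compound_id` and
#'   `smiles` (header required; tab or comma separated).
#' @return named character vector of SMILES.
#' @export
readCompoundTable <- function(file) {
  sep <- if (grepl("\\.tsv$|\\.txt$|\\.smi$", file)) "\t" else ","
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, quote = "\"",
                         comment.char = "")
  stopifnot(all(c("compound_id", "smiles") %in% colnames(d)))
  stats::setNames(d$smiles, d$compound_id)
}

#' Write the curation report of a CompoundSet
#'
#' Emits the delimited report (id, raw, canonical, flags, valid, note).
#'
#' @param x a [CompoundSet].
#' @param file output path.
#' @export
writeCurationReport <- function(x, file) {
  stopifnot(is(x, "CompoundSet"))
  utils::write.table(as.data.frame(x@data), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
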