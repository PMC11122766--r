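# Fixed-length feature vectors per standardized compound. Three schemes:
#   circular_fingerprint - radius-2 circular (Morgan-type) substructure
#     fingerprint hashed to 5120 bits, computed in-package over the
#     molecular graph (atom invariants: atomic number, heavy degree, formal
#     charge, bond-order sum; neighbor environments hashed order-invariantly)
#   structural_keys - the 166 MACCS keys (OpenBabel's SMARTS dictionary)
#   descriptors - a fixed panel of exactly 200 numeric descriptors
# Two inputs with the same canonical structure always map to the same
# vector, and featurization is independent of atom ordering.

.FP_BITS <- 5120L
.FP_RADIUS <- 2L
.MACCS_KEYS <- 166L

.element_z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
                Al = 13, Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20,
                Ti = 22, Cr = 24, Mn = 25, Fe = 26, Co = 27, Ni = 28,
                Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35, Ag = 47,
                Sn = 50, I = 53, Pt = 78, Au = 79, Hg = 80, Pb = 82)

# MDL ctab charge codes: 0 none, 1 +3, 2 +2, 3 +1, 4 radical, 5 -1, 6 -2, 7 -3
.mdl_charge <- c(0, 3, 2, 1, 0, -1, -2, -3)

# order-invariant integer hash of an integer vector, kept < 2^31 - 1
.hash_ints <- function(v) {
  h <- 7
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

# molecular graph from one ChemmineR SDF entry
.sdf_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_[0-9]+$", "", rownames(ab))
  nA <- length(el)
  chg <- rep(0L, nA)
  if ("C5" %in% colnames(ab)) {
    code <- as.integer(ab[, "C5"])
    code[is.na(code) | code < 0 | code > 7] <- 0L
    chg <- as.integer(.mdl_charge[code + 1L])
  }
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bonds <- matrix(integer(0), 0, 3)
  } else {
    bonds <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]),
                   as.integer(bb[, 3L]))
  }
  z <- .element_z[el]
  z[is.na(z)] <- 0
  list(element = el, z = as.integer(z), charge = chg, bonds = bonds,
       n = nA)
}

# circular environment identifiers per atom for radii 0..radius
.morgan_identifiers <- function(graph, radius = .FP_RADIUS) {
  n <- graph$n
  if (n == 0L) return(integer(0))
  nbr <- vector("list", n)
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds[k, 1L]; b <- graph$bonds[k, 2L]
      o <- graph$bonds[k, 3L]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  deg <- vapply(nbr, function(m) if (is.null(m)) 0L else nrow(m), 0L)
  bsum <- vapply(nbr, function(m) if (is.null(m)) 0L else sum(m[, 2L]), 0L)
  inv <- vapply(seq_len(n), function(i)
    .hash_ints(c(graph$z[i], deg[i], graph$charge[i] + 8L, bsum[i])),
    numeric(1))
  ids <- inv
  for (r in seq_len(radius)) {
    newinv <- inv
    for (i in seq_len(n)) {
      m <- nbr[[i]]
      if (is.null(m)) {
        newinv[i] <- .hash_ints(c(r, inv[i]))
        next
      }
      pair <- cbind(m[, 2L], inv[m[, 1L]])
      ord <- order(pair[, 1L], pair[, 2L])
      newinv[i] <- .hash_ints(c(r, inv[i], t(pair[ord, , drop = FALSE])))
    }
    inv <- newinv
    ids <- c(ids, inv)
  }
  unique(as.integer(round(ids)))
}

.smiles_graphs <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  nm <- paste0("m", seq_along(smiles))
  sdfset <- ChemmineR::smiles2sdf(stats::setNames(smiles, nm))
  lapply(seq_along(smiles), function(i) .sdf_graph(sdfset[[i]]))
}

.morgan_matrix <- function(smiles, bits = .FP_BITS, radius = .FP_RADIUS) {
  graphs <- .smiles_graphs(smiles)
  out <- matrix(0L, length(smiles), bits,
                dimnames = list(NULL, sprintf("fp_%04d", seq_len(bits))))
  for (i in seq_along(graphs)) {
    ids <- .morgan_identifiers(graphs[[i]], radius)
    if (length(ids)) out[i, (ids %% bits) + 1L] <- 1L
  }
  out
}

# SMARTS patterns counted in the descriptor panel
.descriptor_smarts <- c(
  hydroxyl = "[OX2H]", ether = "[OX2]([#6])[#6]",
  aldehyde = "[CX3H1]=O", ketone = "[#6][CX3](=O)[#6]",
  carboxylic_acid = "[CX3](=O)[OX2H1]", ester = "[CX3](=O)[OX2][#6]",
  amide = "[NX3][CX3](=O)", primary_amine = "[NX3;H2;!$(NC=O)]",
  secondary_amine = "[NX3;H1;!$(NC=O)]", tertiary_amine = "[NX3]([#6])([#6])[#6]",
  nitro = "[N+](=O)[O-]", nitrile = "[CX2]#N", azo = "[NX2]=[NX2]",
  sulfonyl = "S(=O)(=O)", sulfonamide = "S(=O)(=O)N",
  thiol = "[SX2H]", thioether = "[SX2]([#6])[#6]",
  aromatic_c = "c", aromatic_n = "n", aromatic_o = "o", aromatic_s = "s",
  ring_atom = "[R]", ring5_atom = "[r5]", ring6_atom = "[r6]")

.descriptor_elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
                          "Si", "Se", "As", "Li", "Na", "K", "Mg", "Ca",
                          "Fe", "Zn", "Cu", "Mn", "Al")

.element_class <- function(el) {
  cls <- c(C = "C", N = "N", O = "O", S = "S", P = "P",
           F = "X", Cl = "X", Br = "X", I = "X")
  out <- unname(cls[el])
  out[is.na(out)] <- "Z"
  out
}

.pair_names <- local({
  cl <- c("C", "N", "O", "S", "P", "X", "Z")
  pairs <- character(0)
  for (i in seq_along(cl)) for (j in i:length(cl))
    pairs <- c(pairs, paste0(cl[i], cl[j]))
  pairs
})

.descriptor_names <- function() {
  c("MW", "exact_mass", "logP", "TPSA", "MR", "HBD", "HBA1", "HBA2", "nF_ob",
    "n_heavy", "n_bonds", "n_rings", "mean_degree",
    "max_degree", "n_hetero", "frac_hetero", "n_halogen", "net_charge",
    "n_pos_charge", "n_neg_charge", "bond_order_sum",
    paste0("count_", .descriptor_elements), "count_other_element",
    paste0("degree_", 1:6),
    "bonds_single", "bonds_double", "bonds_triple",
    paste0("pair_", rep(.pair_names, each = 3), "_o", 1:3),
    paste0("grp_", names(.descriptor_smarts)),
    paste0("env_", sprintf("%02d", 1:32)),
    "mw_per_heavy", "bonds_per_atom", "frac_aromatic", "frac_ring",
    "mean_bond_order", "frac_charged")
}

# one graph -> the graph-derived block of the descriptor panel
.graph_descriptors <- function(g) {
  deg <- integer(g$n); bsum <- integer(g$n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds[k, 1L]; b <- g$bonds[k, 2L]; o <- g$bonds[k, 3L]
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      bsum[a] <- bsum[a] + o; bsum[b] <- bsum[b] + o
    }
  }
  n_comp <- if (g$n == 0L) 0L else {
    # connected components by union-find over bonds
    parent <- seq_len(g$n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (nrow(g$bonds)) for (k in seq_len(nrow(g$bonds))) {
      ra <- find(g$bonds[k, 1L]); rb <- find(g$bonds[k, 2L])
      if (ra != rb) parent[ra] <- rb
    }
    length(unique(vapply(seq_len(g$n), find, 0L)))
  }
  n_rings <- nrow(g$bonds) - g$n + n_comp
  elc <- table(factor(g$element,
                      levels = c(.descriptor_elements, "ZZother")))
  other <- g$n - sum(elc)
  halogens <- sum(g$element %in% c("F", "Cl", "Br", "I"))
  hetero <- sum(!g$element %in% c("C", "H"))
  degh <- tabulate(pmin(deg, 6L), 6L)
  ords <- if (nrow(g$bonds)) tabulate(pmin(g$bonds[, 3L], 3L), 3L) else c(0L, 0L, 0L)
  pair_counts <- stats::setNames(numeric(length(.pair_names) * 3L),
                                 paste0("pair_", rep(.pair_names, each = 3), "_o", 1:3))
  if (nrow(g$bonds)) {
    cls <- .element_class(g$element)
    for (k in seq_len(nrow(g$bonds))) {
      p <- sort(c(cls[g$bonds[k, 1L]], cls[g$bonds[k, 2L]]))
      o <- min(g$bonds[k, 3L], 3L)
      nmk <- paste0("pair_", p[1L], p[2L], "_o", o)
      pair_counts[nmk] <- pair_counts[nmk] + 1
    }
  }
  c(n_heavy = g$n, n_bonds = nrow(g$bonds), n_rings = n_rings,
    mean_degree = if (g$n) mean(deg) else 0,
    max_degree = if (g$n) max(deg) else 0,
    n_hetero = hetero, frac_hetero = if (g$n) hetero / g$n else 0,
    n_halogen = halogens, net_charge = sum(g$charge),
    n_pos_charge = sum(g$charge > 0), n_neg_charge = sum(g$charge < 0),
    bond_order_sum = sum(bsum) / 2,
    stats::setNames(c(as.numeric(elc)[seq_along(.descriptor_elements)], other),
                    c(paste0("count_", .descriptor_elements),
                      "count_other_element")),
    stats::setNames(degh, paste0("degree_", 1:6)),
    bonds_single = ords[1L], bonds_double = ords[2L], bonds_triple = ords[3L],
    pair_counts)
}

# the full 200-descriptor panel for a batch of canonical SMILES
.descriptor_matrix <- function(smiles) {
  nms <- .descriptor_names()
  stopifnot(length(nms) == 200L)
  n <- length(smiles)
  out <- matrix(0, n, 200L, dimnames = list(NULL, nms))
  mols <- .ob_parse(smiles)
  for (i in seq_len(n)) {
    p <- tryCatch(ChemmineOB::prop_OB(mols[[i]]), error = function(e) NULL)
    if (!is.null(p))
      out[i, c("MW", "logP", "TPSA", "MR", "HBD", "HBA1", "HBA2", "nF_ob")] <-
        c(p$MW, p$logP, p$TPSA, p$MR, p$HBD, p$HBA1, p$HBA2, p$nF)
    em <- tryCatch(ChemmineOB::exactMass_OB(mols[i]), error = function(e) NA)
    out[i, "exact_mass"] <- em[[1L]]
  }
  for (k in seq_along(.descriptor_smarts)) {
    out[, paste0("grp_", names(.descriptor_smarts)[k])] <-
      .ob_smarts_count(mols, .descriptor_smarts[[k]])
  }
  graphs <- .smiles_graphs(smiles)
  for (i in seq_len(n)) {
    g <- graphs[[i]]
    gd <- .graph_descriptors(g)
    out[i, names(gd)] <- gd
    ids1 <- .morgan_identifiers(g, radius = 1L)
    env <- tabulate((ids1 %% 32L) + 1L, 32L)
    out[i, paste0("env_", sprintf("%02d", 1:32))] <- env
    nh <- max(g$n, 1L)
    out[i, "mw_per_heavy"] <- out[i, "MW"] / nh
    out[i, "bonds_per_atom"] <- nrow(g$bonds) / nh
    arom <- sum(out[i, c("grp_aromatic_c", "grp_aromatic_n",
                         "grp_aromatic_o", "grp_aromatic_s")])
    out[i, "frac_aromatic"] <- arom / nh
    out[i, "frac_ring"] <- out[i, "grp_ring_atom"] / nh
    bs <- nrow(g$bonds)
    out[i, "mean_bond_order"] <- if (bs) out[i, "bond_order_sum"] / bs else 0
    out[i, "frac_charged"] <- (out[i, "n_pos_charge"] + out[i, "n_neg_charge"]) / nh
  }
  out[!is.finite(out)] <- 0
  out
}

#' Compute fixed-length feature vectors for standardized compounds
#'
#' @param x a [CompoundSet] (all compounds referenced must be valid) or a
#'   character vector of canonical SMILES.
#' @param scheme one of `"circular_fingerprint"` (5120 binary bits, radius
#'   2), `"structural_keys"` (166 MACCS keys) or `"descriptors"` (200
#'   numeric descriptors; non-finite values are imputed as 0).
#' @return numeric matrix, one row per compound (rownames = compound ids),
#'   with a constant number of columns per scheme.
#' @examples
#' \donttest{
#' cs <- standardizeStructures(c(a = "CCO", b = "c1ccccc1O"))
#' dim(featurizeCompounds(cs, "circular_fingerprint"))
#' }
#' @export
featurizeCompounds <- function(x,
                               scheme = c("circular_fingerprint",
                                          "structural_keys", "descriptors")) {
  scheme <- match.arg(scheme)
  if (is(x, "CompoundSet")) {
    bad <- compoundIds(x)[!x@data$valid]
    if (length(bad))
      stop("cannot featurize invalid compounds: ",
           paste(head(bad, 5L), collapse = ", "))
    smiles <- unname(canonicalSmiles(x))
    ids <- compoundIds(x)
  } else {
    smiles <- as.character(x)
    ids <- if (!is.null(names(x))) names(x) else paste0("cpd_", seq_along(x))
  }
  if (length(smiles) == 0L)
    stop("no compounds to featurize")
  m <- switch(scheme,
    circular_fingerprint = .morgan_matrix(smiles),
    structural_keys = {
      mols <- .ob_parse(smiles)
      fp <- ChemmineOB::fingerprint_OB(mols, "MACCS")
      fp <- fp[, seq_len(.MACCS_KEYS), drop = FALSE]
      colnames(fp) <- sprintf("maccs_%03d", seq_len(.MACCS_KEYS))
      fp
    },
    descriptors = .descriptor_matrix(smiles))
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Write a feature matrix as a delimited file
#'
#' @param m feature matrix from [featurizeCompounds()].
#' @param file output path; tab-separated with a header row of feature names
#'   and a leading `compound_id` column.
#' @export
writeFeatureMatrix <- function(m, file) {
  d <- data.frame(compound_id = rownames(m), m, check.names = FALSE)
  utils::write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
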