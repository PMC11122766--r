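# Thin wrappers around the OpenBabel command-line tools. All batch
# conversions go through temporary .smi files with integer titles so that
# molecules which fail a step can be identified: obabel drops unparseable
# records from its output, and the surviving titles tell us which ones.

.ob_available <- function() {
  nzchar(Sys.which("obabel"))
}

.check_openbabel <- function() {
  if (!.ob_available())
    stop("OpenBabel ('obabel') was not found on the PATH; ",
         "structure curation requires it.", call. = FALSE)
}

#' Run one OpenBabel conversion over a batch of SMILES
#'
#' @param smiles character vector of SMILES strings.
#' @param args extra command-line arguments (e.g. `"--neutralize"`).
#' @param out_format output format passed to `-o` (default canonical SMILES).
#' @param tool binary to call, `"obabel"` or `"obtautomer"`.
#' @return character vector aligned with `smiles`; entries that failed to
#'   convert are `NA`.
#' @noRd
.ob_convert <- function(smiles, args = character(), out_format = "can",
                        tool = "obabel") {
  .check_openbabel()
  n <- length(smiles)
  if (n == 0L) return(character(0))
  res <- rep(NA_character_, n)
  todo <- which(!is.na(smiles) & nzchar(smiles))
  if (length(todo) == 0L) return(res)
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles[todo], todo), fin)
  if (tool == "obabel") {
    full_args <- c(fin, paste0("-o", out_format), "-O", fout, "-e", args)
  } else {
    full_args <- c(args, fin)
  }
  out <- suppressWarnings(system2(tool, full_args,
                                  stdout = if (tool == "obabel") FALSE else fout,
                                  stderr = FALSE))
  if (!file.exists(fout)) return(res)
  lines <- readLines(fout, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(res)
  parts <- strsplit(lines, "[\t ]+")
  for (p in parts) {
    if (length(p) >= 2L) {
      idx <- suppressWarnings(as.integer(p[[2L]]))
      if (!is.na(idx) && idx >= 1L && idx <= n) res[idx] <- p[[1L]]
    }
  }
  res
}

#' Canonical SMILES via OpenBabel
#' @noRd
.ob_canonical <- function(smiles) .ob_convert(smiles, character())

# Cache for parsed molecule references and other per-session lookups.
.metabobip_cache <- new.env(parent = emptyenv())

#' Parse SMILES into OpenBabel molecule references (ChemmineOB)
#' @return list of OBMol references, NULL where parsing failed.
#' @noRd
.ob_parse <- function(smiles) {
  if (length(smiles) == 0L) return(list())
  src <- paste(paste0(smiles, "\t", seq_along(smiles)), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", src, identity)
  # forEachMol keeps input order but may drop failures; map back via count
  if (length(mols) == length(smiles)) return(mols)
  # fall back to per-molecule parsing to preserve alignment
  lapply(smiles, function(s) {
    tryCatch(ChemmineOB::forEachMol("SMILES", paste0(s, "\tx"), identity)[[1L]],
             error = function(e) NULL)
  })
}

#' Count SMARTS matches per molecule
#' @noRd
.ob_smarts_count <- function(mols, pattern) {
  if (length(mols) == 0L) return(integer(0))
  ok <- !vapply(mols, is.null, logical(1))
  out <- integer(length(mols))
  if (any(ok)) {
    out[ok] <- as.integer(ChemmineOB::smartsSearch_OB(mols[ok], pattern))
  }
  out
}

#' Deterministic seed fan-out
#'
#' Derives a child seed from a master seed and a label, keeping the result
#' inside the 32-bit integer range. All randomness in the package flows from
#' one run-level seed through this helper.
#'
#' @param seed master integer seed.
#' @param label character tag for the consumer (e.g. an endpoint name).
#' @return an integer seed.
#' @export
childSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}
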