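# Chemistry layer: SMILES standardization and ECFP4 circular fingerprints
# via ChemmineR / ChemmineOB (OpenBabel). Both are optional dependencies;
# everything downstream of fingerprinting (the naive Bayes machinery) works
# on plain integer feature sets and never touches chemistry.

chem_available <- function() {
  requireNamespace("ChemmineR", quietly = TRUE) &&
    requireNamespace("ChemmineOB", quietly = TRUE)
}

need_chem <- function() {
  if (!chem_available())
    stop("ChemmineR and ChemmineOB are required for structure handling; ",
         "install them or supply precomputed fingerprints")
}

#' Standardize a SMILES structure
#'
#' Applies the standardization contract used before fingerprinting:
#' aromatic perception (aromatize), removal of explicit hydrogens,
#' reduction of multi-fragment inputs (salts, mixtures) to the largest
#' fragment by heavy-atom count, neutralization of +1/-1 charges where
#' chemically valid, and canonicalization. The result is idempotent:
#' `standardize_smiles(standardize_smiles(s)) == standardize_smiles(s)`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical standardized SMILES.
#' @export
standardize_smiles <- function(smiles) {
  need_chem()
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(trimws(s)))
      stop("structure error: empty SMILES")
    frags <- strsplit(trimws(s), ".", fixed = TRUE)[[1]]
    can <- vapply(frags, .ob_canonical, character(1))
    if (length(can) > 1L) {
      sizes <- vapply(can, .heavy_atom_count, numeric(1))
      can <- can[which.max(sizes)]  # largest fragment wins; ties keep first
    }
    .ob_canonical(can, neutralize = TRUE)
  }, character(1), USE.NAMES = FALSE)
}

# one SMILES -> canonical SMILES through OpenBabel; dies on parse failure
.ob_canonical <- function(s, neutralize = FALSE) {
  out <- tryCatch({
    if (neutralize)
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"),
                                options = data.frame(names = "neutralize",
                                                     args = ""))
    else
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))
  }, error = function(e) "")
  out <- strsplit(out, "[\t\n]")[[1]][1]
  if (is.na(out) || !nzchar(out))
    stop("structure error: unparseable SMILES '", s, "'")
  out
}

.heavy_atom_count <- function(s) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s)),
                  error = function(e) NULL)
  if (is.null(sdf)) return(0)
  ab <- ChemmineR::atomblock(sdf[[1]])
  sum(!grepl("^H_", rownames(ab)))
}

#' ECFP4 circular fingerprints
#'
#' Extended-connectivity fingerprints of diameter 4 (radius 2): hashed
#' circular substructure features, folded to a 4096-bit space. Identical
#' structures (after [standardize_smiles()]) give identical feature sets.
#' Returned as sparse sets of set-bit identifiers, the representation the
#' naive Bayes target models consume.
#'
#' @param smiles Character vector of standardized SMILES. Elements that are
#'   `NA` or empty are skipped (structureless) and return `NULL` with a flag.
#' @return A named list (by input name or index) of sorted integer feature-id
#'   vectors; structureless entries are `NULL` and listed in attribute
#'   `structureless`.
#' @export
fingerprint_ecfp4 <- function(smiles) {
  need_chem()
  nm <- if (!is.null(names(smiles))) names(smiles) else as.character(seq_along(smiles))
  smiles <- as.character(smiles)
  empty <- is.na(smiles) | !nzchar(trimws(smiles))
  out <- stats::setNames(vector("list", length(smiles)), nm)
  if (any(!empty)) {
    idx <- which(!empty)
    fps <- ChemmineOB::forEachMol(
      "SMILES", paste(smiles[idx], collapse = "\n"),
      function(mol) ChemmineOB::fingerprint_OB(list(mol), "ECFP4"))
    if (length(fps) != length(idx))
      stop("structure error: ", length(idx) - length(fps),
           " SMILES failed to parse during fingerprinting")
    for (k in seq_along(idx))
      out[[idx[k]]] <- as.integer(which(fps[[k]] == 1))
  }
  attr(out, "structureless") <- nm[empty]
  out
}
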