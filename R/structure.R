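# Structure model: a flat atom table (one row per atom) with per-residue
# polymer classification, in the spirit of the bio3d atom data frame.
# Coordinates are in angstrom; residue numbers are author numbering.

PROTEIN_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                      "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                      "PRO", "SER", "THR", "TRP", "TYR", "VAL")
RNA_RESIDUES <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU",
                  "ADE", "CYT", "GUA", "URA")
WATER_RESIDUES <- c("HOH", "WAT", "H2O")

#' Build a structure model from an atom table
#'
#' @param atoms data frame with columns `elety` (atom name), `resid`
#'   (residue name), `chain`, `resno` (author residue number), `x`, `y`,
#'   `z`; optional `elem` (element symbol, inferred from the atom name when
#'   absent), `o` (occupancy, default 1), `b` (B-factor, default 0),
#'   `type` (`"ATOM"`/`"HETATM"`).
#' @return object of class `structure_model`: list with the completed
#'   `atoms` table (including a `polymer` column with values `"protein"`,
#'   `"rna"`, `"water"` or `"het"`) and a `chains` summary.
#' @export
structure_model <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(atoms)) stop("atom table is empty", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  atoms$elety <- toupper(trimws(atoms$elety))
  atoms$resid <- toupper(trimws(atoms$resid))
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(atoms$elem))
    atoms$elem <- guess_element(atoms$elety, atoms$resid)
  atoms$elem <- toupper(trimws(atoms$elem))
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$type))
    atoms$type <- ifelse(atoms$resid %in% c(PROTEIN_RESIDUES, RNA_RESIDUES),
                         "ATOM", "HETATM")
  atoms$polymer <- classify_residue(atoms$resid)
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, resid, atom) keys in atom table",
         call. = FALSE)
  rownames(atoms) <- NULL
  chains <- stats::aggregate(polymer ~ chain, data = atoms,
                             FUN = function(p) {
                               p <- setdiff(unique(p), "water")
                               if (!length(p)) "water"
                               else if (length(p) == 1L) p
                               else "mixed"
                             })
  structure(list(atoms = atoms, chains = chains), class = "structure_model")
}

classify_residue <- function(resid) {
  ifelse(resid %in% PROTEIN_RESIDUES, "protein",
  ifelse(resid %in% RNA_RESIDUES, "rna",
  ifelse(resid %in% WATER_RESIDUES, "water", "het")))
}

# element from PDB atom name: strip digits/primes, first letter, except
# known two-letter ions. CA/NA inside a standard polymer residue are an
# alpha carbon / a base nitrogen, not calcium/sodium, so the ion reading
# is restricted to het residues.
guess_element <- function(elety, resid = NULL) {
  elety <- toupper(trimws(elety))
  two <- c("ZN", "MG", "MN", "FE", "NA", "CL", "CA", "BR")
  polymer <- if (is.null(resid)) rep(FALSE, length(elety)) else
    toupper(trimws(resid)) %in% c(PROTEIN_RESIDUES, RNA_RESIDUES)
  out <- character(length(elety))
  for (i in seq_along(elety)) {
    nm <- gsub("[0-9']", "", elety[i])
    out[i] <- if (nm %in% two && !polymer[i]) nm else substr(nm, 1L, 1L)
  }
  out
}

#' @export
print.structure_model <- function(x, ...) {
  np <- table(factor(x$atoms$polymer,
                     levels = c("protein", "rna", "het", "water")))
  cat("<structure_model> ", nrow(x$atoms), " atoms, ",
      nrow(x$chains), " chains (",
      paste(sprintf("%s %d", names(np), as.integer(np)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Read a PDB file into a structure model
#'
#' Parses ATOM/HETATM records via \pkg{bio3d}; keeps model 1 only and
#' resolves alternate locations to conformer A. HETATM codes such as ZN,
#' MG, ACT and HOH are carried through and classified by residue name.
#'
#' @param path PDB file.
#' @return [structure_model()].
#' @export
read_pdb <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (is.null(at) || !nrow(at))
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  at$chain[is.na(at$chain)] <- " "
  structure_model(data.frame(
    elety = at$elety, resid = at$resid, chain = at$chain,
    resno = at$resno, x = at$x, y = at$y, z = at$z,
    elem = ifelse(is.na(at$elesy) | at$elesy == "",
                  guess_element(at$elety, at$resid), toupper(at$elesy)),
    o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    type = at$type, stringsAsFactors = FALSE))
}

#' Write a structure model to a PDB file
#'
#' @param model [structure_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = at$type,
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, o = at$o, b = at$b, elesy = at$elem)
  invisible(path)
}

#' Select atom indices from a structure model
#'
#' @param model [structure_model()].
#' @param chain,resno,resid,elety,polymer optional filters; each keeps atoms
#'   matching any of the given values.
#' @return integer vector of row indices into `model$atoms`.
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, resid = NULL,
                         elety = NULL, polymer = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  if (!is.null(polymer)) keep <- keep & at$polymer %in% polymer
  which(keep)
}

atom_xyz <- function(model, idx = seq_len(nrow(model$atoms))) {
  as.matrix(model$atoms[idx, c("x", "y", "z"), drop = FALSE])
}

# single named atom of a residue; NULL when absent
residue_atom <- function(model, chain, resno, elety) {
  i <- select_atoms(model, chain = chain, resno = resno, elety = elety)
  if (!length(i)) return(NULL)
  model$atoms[i[1L], , drop = FALSE]
}

#' Apply a rigid-body transform to a structure model
#'
#' @param model [structure_model()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed model.
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- atom_xyz(model) %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, "+")
  model$atoms$x <- xyz[, 1L]
  model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}
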