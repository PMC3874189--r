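# Sequence containers shared by the code predictor, the scanner and the
# mass calculator.

#' Standard amino-acid one-letter alphabet (plus X for unknown)
#' @keywords internal
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Create a protein sequence object
#'
#' A light container for a one-letter protein sequence together with the
#' author numbering of its first residue, so that motif positions can be
#' reported in the numbering used in structure papers (e.g. Lys406).
#'
#' @param id character label for the sequence.
#' @param residues one-letter amino-acid string; whitespace is stripped and
#'   case normalised. Alphabet: the 20 standard residues plus `X`.
#' @param numbering_offset integer author number of the first residue
#'   (default 1). Position `i` of the string is reported as
#'   `numbering_offset + i - 1`.
#' @return an object of class `protein_sequence` with fields `id`,
#'   `residues` and `numbering_offset`.
#' @export
#' @examples
#' protein_sequence("znf", "ACKYACAAAACAAAHAA", numbering_offset = 401)
protein_sequence <- function(id, residues, numbering_offset = 1L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(gsub("[[:space:]*]", "", residues))
  if (!nzchar(residues))
    stop("protein sequence '", id, "' is empty", call. = FALSE)
  letters_seen <- unique(strsplit(residues, "")[[1L]])
  bad <- setdiff(letters_seen, AA_ALPHABET)
  if (length(bad))
    stop("invalid residue letter(s) in '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  numbering_offset <- as.integer(numbering_offset)
  if (is.na(numbering_offset) || numbering_offset < 0L)
    stop("numbering_offset must be a non-negative integer", call. = FALSE)
  structure(list(id = id, residues = residues,
                 numbering_offset = numbering_offset),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$id, ": ", nchar(x$residues),
      " residues, numbering ", x$numbering_offset, "..",
      x$numbering_offset + nchar(x$residues) - 1L, "\n", sep = "")
  invisible(x)
}

#' Create an RNA sequence object
#'
#' Canonicalises a transcript to uppercase `A`/`C`/`G`/`U`; `T` is accepted
#' on input and mapped to `U` so DNA-spelled transcripts scan identically.
#'
#' @param id character label.
#' @param bases base string over A, C, G, U (or T).
#' @return object of class `rna_seq` with fields `id` and `bases`.
#' @export
#' @examples
#' rna_seq("tail", "aaaaaaaat")$bases  # "AAAAAAAAU"
rna_seq <- function(id, bases) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  bases <- chartr("t", "u", tolower(gsub("[[:space:]]", "", bases)))
  bases <- toupper(bases)
  if (!nzchar(bases)) stop("RNA sequence '", id, "' is empty", call. = FALSE)
  bad <- setdiff(unique(strsplit(bases, "")[[1L]]), c("A", "C", "G", "U"))
  if (length(bad))
    stop("invalid base letter(s) in '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(id = id, bases = bases), class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat("<rna_seq> ", x$id, ": ", nchar(x$bases), " nt\n", sep = "")
  invisible(x)
}

# coerce a character or rna_seq/protein_sequence argument
as_rna_seq <- function(x, id = "rna") {
  if (inherits(x, "rna_seq")) return(x)
  rna_seq(id, x)
}

as_protein_sequence <- function(x, id = "protein", numbering_offset = 1L) {
  if (inherits(x, "protein_sequence")) return(x)
  protein_sequence(id, x, numbering_offset)
}
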