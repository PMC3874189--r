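# Theoretical average molar masses of ssRNA, protein chains and their
# complexes, for cross-checking light-scattering stoichiometry.
#
# RNA residue masses are average-isotopic nucleoside-5'-monophosphate
# residues within a chain (nucleotide minus water): A 329.21, C 305.18,
# G 345.21, U 306.17 Da. A chain with free 5'-OH and 3'-OH carries one
# fewer phosphate than residues, so M = sum(residues) - HPO3 + H2O with
# HPO3 = 79.98 and H2O = 18.02 Da. The 5'-phosphate convention keeps the
# extra phosphate: M = sum(residues) + H2O.

RNA_RESIDUE_MASS <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)
MASS_HPO3 <- 79.98
MASS_H2O <- 18.02

# average residue (amino-acid minus water) masses, Da
AA_RESIDUE_MASS <- c(
  G = 57.05, A = 71.08, S = 87.08, P = 97.12, V = 99.13, T = 101.10,
  C = 103.14, L = 113.16, I = 113.16, N = 114.10, D = 115.09, Q = 128.13,
  K = 128.17, E = 129.12, M = 131.19, H = 137.14, F = 147.18, R = 156.19,
  Y = 163.18, W = 186.21)

mass_result <- function(mass, kind, convention, formula) {
  structure(list(mass = mass, kda = mass / 1000, kind = kind,
                 terminal_convention = convention, formula = formula),
            class = "mass_result")
}

#' @export
print.mass_result <- function(x, ...) {
  cat("<mass_result> ", x$kind, ": ", format(x$mass, digits = 8), " Da (",
      format(round(x$kda, 1), nsmall = 1), " kDa)",
      if (!is.na(x$terminal_convention))
        paste0(" [", x$terminal_convention, "]") else "",
      "\n  ", x$formula, "\n", sep = "")
  invisible(x)
}

#' Theoretical average mass of a single-stranded RNA
#'
#' @param seq [rna_seq()] or base string.
#' @param convention `"5'-OH/3'-OH"` (default; a synthesised
#'   oligonucleotide with free hydroxyl termini) or `"5'-P/3'-OH"`.
#' @return [mass_result] object; `mass` in Da, `kda` in kDa. Each internal
#'   adenosine contributes 329.21 Da.
#' @export
#' @examples
#' round(rna_mass("AAAAAAAA")$kda, 1)  # 2.6
rna_mass <- function(seq, convention = c("5'-OH/3'-OH", "5'-P/3'-OH")) {
  seq <- as_rna_seq(seq)
  convention <- match.arg(convention)
  bases <- strsplit(seq$bases, "")[[1L]]
  res_sum <- sum(RNA_RESIDUE_MASS[bases])
  m <- if (convention == "5'-OH/3'-OH")
    res_sum - MASS_HPO3 + MASS_H2O else res_sum + MASS_H2O
  counts <- table(factor(bases, levels = names(RNA_RESIDUE_MASS)))
  formula <- paste0(
    paste(sprintf("%d x %s(%.2f)", as.integer(counts), names(counts),
                  RNA_RESIDUE_MASS)[counts > 0], collapse = " + "),
    if (convention == "5'-OH/3'-OH")
      sprintf(" - HPO3(%.2f) + H2O(%.2f)", MASS_HPO3, MASS_H2O)
    else sprintf(" + H2O(%.2f)", MASS_H2O))
  mass_result(m, paste0("ssRNA ", seq$id, " (", length(bases), " nt)"),
              convention, formula)
}

#' Theoretical average mass of a protein chain
#'
#' @param seq [protein_sequence()] or residue string; `X` is rejected
#'   because its mass is undefined.
#' @return [mass_result] object: sum of average residue masses plus one
#'   water.
#' @export
#' @examples
#' protein_mass("G")$mass  # 75.07, free glycine
protein_mass <- function(seq) {
  seq <- as_protein_sequence(seq)
  res <- strsplit(seq$residues, "")[[1L]]
  if ("X" %in% res)
    stop("sequence contains X; mass undefined", call. = FALSE)
  m <- sum(AA_RESIDUE_MASS[res]) + MASS_H2O
  mass_result(m, paste0("protein ", seq$id, " (", length(res), " aa)"),
              NA_character_,
              sprintf("sum of %d residue masses + H2O(%.2f)",
                      length(res), MASS_H2O))
}

#' Mass of a complex as the sum of its parts
#'
#' Sums are reported unrounded; kDa rounding (one decimal) is applied only
#' at print time.
#'
#' @param parts list of [mass_result] objects (at least one).
#' @return [mass_result] for the complex.
#' @export
complex_mass <- function(parts) {
  if (inherits(parts, "mass_result")) parts <- list(parts)
  if (!length(parts)) stop("no parts given", call. = FALSE)
  if (!all(vapply(parts, inherits, logical(1), "mass_result")))
    stop("all parts must be mass_result objects", call. = FALSE)
  m <- sum(vapply(parts, function(p) p$mass, numeric(1)))
  mass_result(m, sprintf("complex of %d part(s)", length(parts)),
              NA_character_,
              paste(vapply(parts, function(p)
                format(p$mass, digits = 8), character(1)),
                collapse = " + "))
}
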