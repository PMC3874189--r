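# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-spiral point set (no RNG), and interface buried area.

#' Deterministic unit-sphere point set (golden spiral)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
golden_spiral_points <- function(n) {
  stopifnot(n >= 1L)
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- i * pi * (3 - sqrt(5))   # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

sasa_radii_for <- function(model, radii) {
  elem <- model$atoms$elem
  r <- unname(radii[elem])
  if (any(is.na(r))) {
    missing <- unique(elem[is.na(r)])
    warning("no van der Waals radius for element(s) ",
            paste(missing, collapse = ", "), "; using 1.70 angstrom",
            call. = FALSE)
    r[is.na(r)] <- 1.70
  }
  r
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom is expanded by the probe radius and covered with a fixed
#' golden-spiral point set; the accessible fraction is the fraction of
#' points outside every neighbouring expanded sphere. Fully deterministic
#' for a given point count.
#'
#' @param model [structure_model()], or an n x 3 coordinate matrix (then
#'   `radii_vec` must give per-atom radii).
#' @param probe probe radius in angstrom (default 1.4).
#' @param n_points sphere points per atom (default 960).
#' @param radii named element radius table (angstrom).
#' @param subset optional atom index vector; area of those atoms in the
#'   context of *only* those atoms (i.e. the subset extracted as its own
#'   molecule).
#' @param radii_vec per-atom radii when `model` is a bare matrix.
#' @return list of class `sasa_result`: `total` (square angstrom),
#'   `per_atom`, `probe`, `n_points`, `radii_table_id`.
#' @export
compute_sasa <- function(model, probe = default_config()$sasa$probe,
                         n_points = default_config()$sasa$n_points,
                         radii = default_config()$sasa$radii,
                         subset = NULL, radii_vec = NULL) {
  if (inherits(model, "structure_model")) {
    xyz <- atom_xyz(model)
    rad <- sasa_radii_for(model, radii)
  } else {
    xyz <- as.matrix(model)
    if (is.null(radii_vec))
      stop("radii_vec required for bare coordinate input", call. = FALSE)
    rad <- radii_vec
  }
  if (!is.null(subset)) {
    xyz <- xyz[subset, , drop = FALSE]
    rad <- rad[subset]
  }
  n <- nrow(xyz)
  if (!n) stop("empty atom set", call. = FALSE)
  if (probe <= 0) stop("probe radius must be positive", call. = FALSE)
  sphere <- golden_spiral_points(n_points)
  rext <- rad + probe
  per_atom <- numeric(n)
  # pairwise distance prefilter: only neighbours can occlude
  for (i in seq_len(n)) {
    pts <- sweep(sphere * rext[i], 2L, xyz[i, ], "+")
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rext + rext[i])^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rext[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * rext[i]^2 * sum(acc) / n_points
  }
  structure(list(total = sum(per_atom), per_atom = per_atom,
                 probe = probe, n_points = as.integer(n_points),
                 radii_table_id = "polyAcode-vdw-1"),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<sasa_result> total ", format(x$total, digits = 6),
      " A^2 over ", length(x$per_atom), " atoms (probe ", x$probe,
      " A, ", x$n_points, " points)\n", sep = "")
  invisible(x)
}

#' Buried surface area between two atom groups
#'
#' `SASA(A alone) + SASA(B alone) - SASA(A union B)`: the interface area
#' that becomes solvent-inaccessible on complex formation. Symmetric in
#' group order and zero (up to point-set resolution) for separated groups.
#'
#' @param model [structure_model()].
#' @param group_a,group_b disjoint atom index vectors (see
#'   [select_atoms()]).
#' @inheritParams compute_sasa
#' @return buried area in square angstrom (clamped at 0).
#' @export
compute_buried_area <- function(model, group_a, group_b,
                                probe = default_config()$sasa$probe,
                                n_points = default_config()$sasa$n_points,
                                radii = default_config()$sasa$radii) {
  stopifnot(inherits(model, "structure_model"))
  if (length(intersect(group_a, group_b)))
    stop("groups overlap", call. = FALSE)
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  sa <- compute_sasa(model, probe, n_points, radii, subset = group_a)$total
  sb <- compute_sasa(model, probe, n_points, radii, subset = group_b)$total
  sab <- compute_sasa(model, probe, n_points, radii,
                      subset = c(group_a, group_b))$total
  max(0, sa + sb - sab)
}
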