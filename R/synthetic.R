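# Seeded synthetic-fixture generators: finger sequences of defined code
# class, idealised 3D contact geometries for every contact category, toy
# finger-RNA mini complexes with known ground truth, and transcripts with
# planted motifs. All randomness goes through withr::with_seed with an
# explicit integer seed; the same spec and seed give byte-identical
# output.
#
# Idealised geometry uses planar canonical ring templates (regular hexagon
# of bond length 1.39 angstrom; the purine five-membered ring completed as
# a regular pentagon on the C4-C5 edge; exocyclic N6 at 1.34 angstrom).
# These are not force-field geometries: they realise the *detection*
# geometry (distances, planarity, angles) exactly.

# ---- planar templates (z = 0), six-ring centred at the origin ----------

adenine_template <- function() {
  hex <- ring_hexagon(1.39)
  rownames(hex) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  n6 <- hex["C6", ] + 1.34 * unit(hex["C6", ])
  # five-ring as a regular pentagon fused on the C4-C5 edge, outside
  pent <- pentagon_on_edge(hex["C4", ], hex["C5", ])
  rbind(hex, N6 = n6, N7 = pent$n7, C8 = pent$c8, N9 = pent$n9)
}

ring_hexagon <- function(bond) {
  ang <- (0:5) * pi / 3
  cbind(bond * cos(ang), bond * sin(ang), 0)
}

pentagon_on_edge <- function(p4, p5) {
  s <- vnorm(p5 - p4)
  r5 <- s / (2 * sin(pi / 5))
  apothem <- r5 * cos(pi / 5)
  mid <- (p4 + p5) / 2
  out <- unit(mid)          # outward from the hexagon centre (origin)
  ctr <- mid + apothem * out
  a5 <- atan2(p5[2] - ctr[2], p5[1] - ctr[1])
  step <- -2 * pi / 5       # walk away from p4 (which sits at a5 + 72 deg)
  vert <- function(k) ctr + r5 * c(cos(a5 + k * step), sin(a5 + k * step), 0)
  list(n7 = vert(1), c8 = vert(2), n9 = vert(3))
}

phe_ring_template <- function() {
  hex <- ring_hexagon(1.39)
  rownames(hex) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  hex
}

atoms_row <- function(elety, resid, chain, resno, xyz, type = "ATOM") {
  data.frame(elety = elety, resid = resid, chain = chain, resno = resno,
             x = xyz[1L], y = xyz[2L], z = xyz[3L], type = type,
             stringsAsFactors = FALSE)
}

template_rows <- function(tpl, resid, chain, resno, type = "ATOM") {
  do.call(rbind, lapply(rownames(tpl), function(nm)
    atoms_row(nm, resid, chain, resno, tpl[nm, ], type)))
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3,
         byrow = TRUE)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

transform_tpl <- function(tpl, rotation = diag(3), shift = c(0, 0, 0)) {
  out <- tpl %*% t(rotation)
  out <- sweep(out, 2L, shift, "+")
  rownames(out) <- rownames(tpl)
  out
}

tetrahedral_units <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

# ---- contact fixtures --------------------------------------------------

#' Generate an idealised single-contact fixture
#'
#' Builds a minimal atom set realising one contact geometry exactly, for
#' calibrating and boundary-testing the detectors.
#'
#' Kinds and their parameters (all distances angstrom, angles degrees):
#' \describe{
#'   \item{`stack_pair`}{`distance` between ring centroids (3.5),
#'     `angle` interplanar tilt (0), `offset` lateral displacement (0):
#'     a Phe ring and an adenine six-ring.}
#'   \item{`hbond_pair`}{`distance` N6 to SG (3.3); `with_zn = TRUE` adds
#'     a Zn atom 2.3 angstrom beyond the SG so the cysteine is
#'     Zn-coordinating (category `N6->SG_ZnCys`); with `FALSE` the SG is
#'     free and the bond classifies as `other`.}
#'   \item{`zn_site`}{`d_s` Zn-SG (2.30) and `d_n` Zn-NE2 (2.10) on
#'     tetrahedral directions: three cysteines and one histidine.}
#'   \item{`cation_pi`}{`distance` centroid to Lys NZ (4.5),
#'     `axial_angle` from the ring normal (0).}
#'   \item{`water_bridge`}{`distance` water O to each of two adenine N6
#'     atoms (2.9), the adenines belonging to different residues.}
#' }
#' With `decoys = TRUE` a far-away copy of the partner (20 angstrom out)
#' is added; it must never be detected.
#'
#' @param kind one of the kinds above.
#' @param distance,angle,offset,axial_angle,d_s,d_n geometry parameters.
#' @param with_zn logical (hbond_pair only).
#' @param decoys logical; add out-of-threshold decoy atoms.
#' @return [structure_model()].
#' @export
make_contact_fixture <- function(kind = c("stack_pair", "hbond_pair",
                                          "zn_site", "cation_pi",
                                          "water_bridge"),
                                 distance = NULL, angle = 0, offset = 0,
                                 axial_angle = 0, d_s = 2.30, d_n = 2.10,
                                 with_zn = TRUE, decoys = FALSE) {
  kind <- match.arg(kind)
  rows <- switch(kind,
    stack_pair = fixture_stack(distance %||% 3.5, angle, offset),
    hbond_pair = fixture_hbond(distance %||% 3.3, with_zn),
    zn_site = fixture_zn_site(d_s, d_n),
    cation_pi = fixture_cation_pi(distance %||% 4.5, axial_angle),
    water_bridge = fixture_water_bridge(distance %||% 2.9))
  if (decoys) rows <- rbind(rows, fixture_decoys(kind))
  structure_model(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_stack <- function(distance, angle, offset) {
  phe <- template_rows(phe_ring_template(), "PHE", "A", 10L)
  ade_tpl <- transform_tpl(adenine_template(), rot_x(angle),
                           c(offset, 0, distance))
  rbind(phe, template_rows(ade_tpl, "A", "R", 1L))
}

fixture_hbond <- function(distance, with_zn) {
  ade <- adenine_template()
  dir <- unit(ade["N6", ] - ade["C6", ])
  sg <- ade["N6", ] + distance * dir
  rows <- rbind(template_rows(ade, "A", "R", 1L),
                atoms_row("SG", "CYS", "A", 5L, sg))
  if (with_zn) {
    zn <- sg + 2.30 * dir
    rows <- rbind(rows, atoms_row("ZN", "ZN", "A", 90L, zn, "HETATM"))
  }
  rows
}

fixture_zn_site <- function(d_s, d_n) {
  u <- tetrahedral_units()
  rows <- atoms_row("ZN", "ZN", "A", 90L, c(0, 0, 0), "HETATM")
  for (k in 1:3)
    rows <- rbind(rows, atoms_row("SG", "CYS", "A", k, d_s * u[k, ]))
  rbind(rows, atoms_row("NE2", "HIS", "A", 4L, d_n * u[4L, ]))
}

fixture_cation_pi <- function(distance, axial_angle) {
  a <- axial_angle * pi / 180
  nz <- c(distance * sin(a), 0, distance * cos(a))
  rbind(template_rows(adenine_template(), "A", "R", 1L),
        atoms_row("NZ", "LYS", "A", 20L, nz))
}

fixture_water_bridge <- function(distance) {
  ade <- adenine_template()
  # orient so the centroid->N6 direction points at the origin (the water)
  n6_ang <- atan2(ade["N6", 2L], ade["N6", 1L]) * 180 / pi
  oriented <- transform_tpl(ade, rot_z(180 - n6_ang))
  ctr_off <- vnorm(ade["N6", ])
  a1 <- transform_tpl(oriented, diag(3), c(distance + ctr_off, 0, 0))
  a2 <- transform_tpl(a1, rot_z(180))
  rbind(template_rows(a1, "A", "R", 1L),
        template_rows(a2, "A", "R", 2L),
        atoms_row("O", "HOH", "W", 100L, c(0, 0, 0), "HETATM"))
}

fixture_decoys <- function(kind) {
  far <- c(20, 20, 20)
  switch(kind,
    stack_pair = template_rows(
      transform_tpl(phe_ring_template(), diag(3), far), "PHE", "A", 11L),
    hbond_pair = atoms_row("SG", "CYS", "A", 6L, far),
    zn_site = atoms_row("SG", "CYS", "A", 7L, far),
    cation_pi = atoms_row("NZ", "LYS", "A", 21L, far),
    water_bridge = atoms_row("O", "HOH", "W", 101L, far, "HETATM"))
}

# ---- mini complex ------------------------------------------------------

# place one adenine bound to ligand SG number j of a Zn site at `origin`:
# N6 sits `d_hb` beyond the SG on the outward radial u, the base plane
# contains u, and an in-plane twist `tau` leans the Watson-Crick (tau < 0)
# or Hoogsteen (tau > 0) edge towards the Zn.
place_bound_adenine <- function(origin, u, v, d_site, d_hb, tau) {
  ade <- adenine_template()
  q <- origin + (d_site + d_hb) * u      # world position of N6
  a_dir <- unit(ade["C6", ] - ade["N6", ])  # template N6->C6 direction
  p_dir <- c(-a_dir[2L], a_dir[1L], 0)      # in-plane perpendicular
  ct <- cos(tau * pi / 180); st <- sin(tau * pi / 180)
  world <- matrix(0, nrow(ade), 3L, dimnames = list(rownames(ade), NULL))
  for (nm in rownames(ade)) {
    rel <- ade[nm, ] - ade["N6", ]
    rel2 <- c(rel[1L] * ct - rel[2L] * st, rel[1L] * st + rel[2L] * ct,
              0)
    world[nm, ] <- q + (sum(rel2 * a_dir)) * u + (sum(rel2 * p_dir)) * v
  }
  world
}

# normal of the placed base plane (u and v span it)
site_normal <- function(u, v) unit(pracma_cross(u, v))

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Generate a toy finger-array/RNA complex with known ground truth
#'
#' Builds one idealised binding module per requested finger: a tetrahedral
#' CCCH Zn site, an aromatic (Phe) platform per planted adenine stacked
#' 3.4 angstrom below the base, an N6 to Zn-cysteine-SG hydrogen bond
#' (3.3 angstrom), a backbone amide reading N1 (Watson-Crick-facing bases)
#' or N7 (Hoogsteen-facing bases) at 3.0 angstrom, and a Lys NZ over the
#' opposite base face (cation-pi, 4.5 angstrom axial). Fingers are spaced
#' 30 angstrom apart so no cross-module contact exists. Finger residue
#' numbering follows the default CCCH spacing (c1, c1+6, c1+11, c1+15).
#'
#' @param stoichiometries integer vector over \{0, 1, 2\}: adenines
#'   planted per finger, e.g. `c(2, 1, 2)`.
#' @param seed integer seed (orients each module with a random rotation).
#' @return list with `model` ([structure_model()]), `fingers` (data frame
#'   `finger`, `chain`, `c1`, `c2`, `c3`, `h`) and `truth`: planted
#'   per-finger base counts, per-base edges, and expected contact tallies
#'   (`n_stacking`, `n_n6_sg`, `n_amide`, `n_cation_pi`, `n_zn_sites`).
#' @export
make_mini_complex <- function(stoichiometries = c(2L, 1L, 2L), seed = 1L) {
  stoichiometries <- as.integer(stoichiometries)
  stopifnot(all(stoichiometries %in% 0:2), length(stoichiometries) >= 1L)
  withr::with_seed(as.integer(seed), {
    rows <- list(); fingers <- list(); edges <- character()
    rna_resno <- 0L
    for (i in seq_along(stoichiometries)) {
      k <- stoichiometries[i]
      origin <- c(30 * (i - 1L), 0, 0)
      base_res <- 100L * i
      c1 <- base_res; c2 <- base_res + 6L; c3 <- base_res + 11L
      h <- base_res + 15L
      fingers[[i]] <- data.frame(finger = paste0("F", i), chain = "A",
                                 c1 = c1, c2 = c2, c3 = c3, h = h,
                                 stringsAsFactors = FALSE)
      # random module orientation: a random rotation of the tetrad
      rmat <- random_rotation()
      u <- tetrahedral_units() %*% t(rmat)
      cys_res <- c(c1, c2, c3)
      for (kk in 1:3)
        rows[[length(rows) + 1L]] <- atoms_row(
          "SG", "CYS", "A", cys_res[kk], origin + 2.30 * u[kk, ])
      rows[[length(rows) + 1L]] <- atoms_row(
        "NE2", "HIS", "A", h, origin + 2.10 * u[4L, ])
      rows[[length(rows) + 1L]] <- atoms_row(
        "ZN", "ZN", "A", 9000L + i, origin, "HETATM")
      if (k == 0L) next
      aro_res <- if (k == 2L) c(c1 + 2L, c3 + 2L) else c(c3 + 2L)
      taus <- if (k == 2L) c(-25, 25) else 25   # WC then HG; single = HG
      amide_res <- if (k == 2L) c(c1 + 1L, c2 + 1L) else c(c1 + 1L)
      amide_resid <- if (k == 2L) c("LYS", "ALA") else "LYS"
      for (j in seq_len(k)) {
        uj <- u[j, ]
        vj <- unit(pracma_cross(uj, u[4L, ]))  # in-plane partner axis
        ade <- place_bound_adenine(origin, uj, vj, 2.30, 3.30, taus[j])
        rna_resno <- rna_resno + 1L
        for (nm in rownames(ade))
          rows[[length(rows) + 1L]] <- atoms_row(nm, "A", "R", rna_resno,
                                                 ade[nm, ])
        # stacking platform 3.4 below the base plane
        nrm <- site_normal(uj, vj)
        ctr <- colMeans(ade[c("N1", "C2", "N3", "C4", "C5", "C6"), ])
        ring <- ring_in_plane(phe_ring_template(), uj, vj,
                              ctr - 3.4 * nrm)
        for (nm in rownames(ring))
          rows[[length(rows) + 1L]] <- atoms_row(nm, "PHE", "A",
                                                 aro_res[j], ring[nm, ])
        # cation over the opposite face
        rows[[length(rows) + 1L]] <- atoms_row(
          "NZ", "LYS", "A", 8000L + 10L * i + j, ctr + 4.5 * nrm)
        # backbone amide reading N1 (WC) or N7 (HG)
        target <- if (taus[j] < 0) "N1" else "N7"
        w <- unit(ade[target, ] - ctr)
        n_pos <- ade[target, ] + 3.0 * w
        rows[[length(rows) + 1L]] <- atoms_row("N", amide_resid[j], "A",
                                               amide_res[j], n_pos)
        rows[[length(rows) + 1L]] <- atoms_row("CA", amide_resid[j], "A",
                                               amide_res[j],
                                               n_pos + 1.5 * w)
        edges <- c(edges,
                   if (taus[j] < 0) "WatsonCrick" else "Hoogsteen")
      }
    }
    fingers <- do.call(rbind, fingers)
    n_bases <- sum(stoichiometries)
    truth <- list(
      bases_per_finger = stats::setNames(stoichiometries, fingers$finger),
      edges = edges,
      n_stacking = n_bases, n_n6_sg = n_bases, n_amide = n_bases,
      n_cation_pi = n_bases, n_zn_sites = length(stoichiometries))
    model <- if (length(rows)) structure_model(do.call(rbind, rows))
    else stop("empty complex", call. = FALSE)
    list(model = model, fingers = fingers, truth = truth)
  })
}

# embed a planar template into the plane spanned by (u, v) at `centre`
ring_in_plane <- function(tpl, u, v, centre) {
  out <- matrix(0, nrow(tpl), 3L, dimnames = list(rownames(tpl), NULL))
  for (nm in rownames(tpl))
    out[nm, ] <- centre + tpl[nm, 1L] * u + tpl[nm, 2L] * v
  out
}

#' Random proper rotation matrix
#'
#' Drawn via QR decomposition of a Gaussian matrix with the sign fixed to
#' det +1; uses the current RNG state (seed it with [withr::with_seed()]).
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- diag(sign(diag(qr.R(qr_dec))))
  q <- q %*% d
  if (det(q) < 0) q[, 3L] <- -q[, 3L]
  q
}

# ---- sequence generators -----------------------------------------------

FILLER_AA <- c("A", "D", "E", "G", "I", "N", "P", "Q", "S", "T", "V", "M")

#' Generate a CCCH finger sequence of a requested code class
#'
#' Builds a sequence whose extracted features match the class exactly:
#' `two_aromatic` (aromatic at both code positions, predicts 2),
#' `one_aromatic_c1` / `one_aromatic_c3` (predicts 1), `none` (predicts 0)
#' and `leu_his` (Leu after the first Cys with His two after the third
#' Cys, the finger-1-style exception, predicts 2). Filler residues are
#' drawn from a neutral alphabet containing no Cys, His, aromatic or basic
#' letters, so no spurious motif or feature can arise.
#'
#' @param class code class (see above).
#' @param loops integer loop lengths `(c2-c1-1, c3-c2-1, h-c3-1)`;
#'   default `c(5, 4, 3)`, inside the default spacing bounds.
#' @param seed integer seed.
#' @param flank residues of neutral flank either side (default 5).
#' @return [protein_sequence()] with attribute `"code_class"`.
#' @export
make_finger_sequence <- function(class = c("two_aromatic",
                                           "one_aromatic_c1",
                                           "one_aromatic_c3", "none",
                                           "leu_his"),
                                 loops = c(5L, 4L, 3L), seed = 1L,
                                 flank = 5L) {
  class <- match.arg(class)
  loops <- as.integer(loops)
  stopifnot(length(loops) == 3L, all(loops >= 2L))
  withr::with_seed(as.integer(seed), {
    n <- flank + 1L + loops[1L] + 1L + loops[2L] + 1L + loops[3L] + 1L +
      flank
    res <- sample(FILLER_AA, n, replace = TRUE)
    c1 <- flank + 1L
    c2 <- c1 + loops[1L] + 1L
    c3 <- c2 + loops[2L] + 1L
    h <- c3 + loops[3L] + 1L
    res[c(c1, c2, c3)] <- "C"
    res[h] <- "H"
    res[c1 + 1L] <- if (class == "leu_his") "L" else "K"
    aromatic_pick <- function() sample(c("F", "Y", "W"), 1L)
    if (class %in% c("two_aromatic", "one_aromatic_c1"))
      res[c1 + 2L] <- aromatic_pick()
    if (class %in% c("two_aromatic", "one_aromatic_c3"))
      res[c3 + 2L] <- aromatic_pick()
    if (class == "leu_his") res[c3 + 2L] <- "H"
    out <- protein_sequence(paste0("synthetic_", class, "_seed", seed),
                            paste(res, collapse = ""))
    attr(out, "code_class") <- class
    out
  })
}

#' Generate a tandem array of code-class fingers
#'
#' Concatenates [make_finger_sequence()] spans with neutral linkers.
#'
#' @param classes character vector of code classes, one per finger.
#' @param seed integer seed.
#' @param linker neutral residues between fingers (default 6).
#' @return [protein_sequence()] with attribute `"code_classes"`.
#' @export
make_finger_array <- function(classes, seed = 1L, linker = 6L) {
  withr::with_seed(as.integer(seed), {
    pieces <- character(length(classes))
    for (i in seq_along(classes)) {
      fs <- make_finger_sequence(classes[i],
                                 seed = sample.int(1e6, 1L))
      pieces[i] <- fs$residues
    }
    glue <- vapply(seq_len(length(classes) - 1L), function(i)
      paste(sample(FILLER_AA, linker, replace = TRUE), collapse = ""),
      character(1))
    resid_str <- paste0(pieces[1L],
                        paste0(glue, pieces[-1L], collapse = ""))
    out <- protein_sequence(paste0("synthetic_array_seed", seed),
                            resid_str)
    attr(out, "code_classes") <- classes
    out
  })
}

#' Generate a random transcript with planted motifs
#'
#' Background bases are i.i.d. from `composition`; motifs are then written
#' over the background at the requested 0-based positions.
#'
#' @param length transcript length (nt).
#' @param composition named probabilities for A, C, G, U (default
#'   uniform).
#' @param planted list of `list(motif = , at = )` entries; `at` is the
#'   0-based start.
#' @param seed integer seed.
#' @param id sequence label.
#' @return [rna_seq()].
#' @export
#' @examples
#' tx <- make_transcript(100, planted = list(
#'   list(motif = "AAAAAAAAAAAG", at = 40)), seed = 3)
#' find_exact_motif(tx, "AAAAAAAAAAAG")
make_transcript <- function(length, composition = c(A = 0.25, C = 0.25,
                                                    G = 0.25, U = 0.25),
                            planted = list(), seed = 1L,
                            id = paste0("synthetic_tx_seed", seed)) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  composition <- composition[c("A", "C", "G", "U")]
  if (any(is.na(composition)) || any(composition < 0) ||
      sum(composition) <= 0)
    stop("composition must give non-negative A, C, G, U weights",
         call. = FALSE)
  withr::with_seed(as.integer(seed), {
    bases <- sample(c("A", "C", "G", "U"), length, replace = TRUE,
                    prob = composition / sum(composition))
    for (p in planted) {
      motif <- strsplit(as_rna_seq(p$motif, "motif")$bases, "")[[1L]]
      at <- as.integer(p$at)   # 0-based
      if (at < 0L || at + length(motif) > length)
        stop("planted motif does not fit at position ", at,
             call. = FALSE)
      bases[(at + 1L):(at + length(motif))] <- motif
    }
    rna_seq(id, paste(bases, collapse = ""))
  })
}

# ---- reference-style reconstructions ----------------------------------

#' Synthetic stand-in for C. thermophilum Nab2 Zn fingers 3-5
#'
#' A 66-residue reconstruction of the finger 3-5 region (author numbering
#' 401-466). Every residue that the structural literature names is placed
#' at its author-numbered position -- Cys405/Lys406/Tyr407, Cys411/Ala412,
#' Cys416, Phe418 and His420 (finger 3); Cys426/Arg427, Cys432, Cys437,
#' Phe439, His441 (finger 4); Pro445, Cys446/Lys447/Phe448, Cys451/Thr452,
#' Cys456, Phe458, His460 (finger 5) -- with a fixed neutral filler
#' elsewhere. This is a synthetic sequence, not the database record: use
#' it for exercising the finger code, not for homology work.
#'
#' @return [protein_sequence()] with `numbering_offset = 401`.
#' @export
#' @examples
#' calls <- call_finger_array(nab2_ct_znf35_synthetic())
#' calls$n_adenosines  # 2 1 2
nab2_ct_znf35_synthetic <- function() {
  filler <- strsplit("GSTAGDNQSEVT", "")[[1L]]
  res <- filler[((0:65) %% length(filler)) + 1L]
  put <- function(res, author_pos, aa) {
    res[author_pos - 400L] <- aa
    res
  }
  anchors <- c(`405` = "C", `406` = "K", `407` = "Y", `411` = "C",
               `412` = "A", `416` = "C", `418` = "F", `420` = "H",
               `426` = "C", `427` = "R", `432` = "C", `437` = "C",
               `439` = "F", `441` = "H", `445` = "P", `446` = "C",
               `447` = "K", `448` = "F", `451` = "C", `452` = "T",
               `456` = "C", `458` = "F", `460` = "H")
  for (pos in names(anchors))
    res <- put(res, as.integer(pos), anchors[[pos]])
  protein_sequence("Ct_Nab2_ZnF3-5_synthetic",
                   paste(res, collapse = ""), numbering_offset = 401L)
}

#' Synthetic five-finger C. thermophilum-style Nab2 array
#'
#' A full-array analogue with the conservation pattern of the five-finger
#' C-terminal domain: odd-numbered fingers carry the basic and both
#' aromatic code residues (two adenosines each), even-numbered fingers
#' only the aromatic after the third cysteine (one adenosine each).
#' Synthetic: generated by [make_finger_array()], not a database record.
#'
#' @param seed integer seed.
#' @return [protein_sequence()].
#' @export
nab2_ct_array_synthetic <- function(seed = 1L) {
  make_finger_array(c("two_aromatic", "one_aromatic_c3", "two_aromatic",
                      "one_aromatic_c3", "two_aromatic"), seed = seed)
}

#' Synthetic S. cerevisiae-style Nab2 fingers 5-7 array
#'
#' Three-finger analogue of the high-affinity module: fingers 5 and 7
#' two-aromatic, finger 6 single-aromatic, so the array capacity is five
#' adenosines. Synthetic: generated by [make_finger_array()].
#'
#' @param seed integer seed.
#' @return [protein_sequence()].
#' @export
nab2_sc_znf57_synthetic <- function(seed = 1L) {
  make_finger_array(c("two_aromatic", "one_aromatic_c3", "two_aromatic"),
                    seed = seed)
}

#' Write FASTA and PDB fixture files for a standard test set
#'
#' Convenience for the command-line `make-fixtures` entry point: writes
#' the synthetic finger 3-5 sequence, a five-finger array, a transcript
#' with a planted A-rich motif, and a (2,1,2) mini-complex PDB into a
#' directory.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return character vector of the files written, invisibly.
#' @export
write_fixture_set <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "ct_znf35_synthetic.fasta")
  write_fasta(list(nab2_ct_znf35_synthetic()), f1)
  f2 <- file.path(dir, "ct_array_synthetic.fasta")
  write_fasta(list(nab2_ct_array_synthetic(seed)), f2)
  tx <- make_transcript(500, planted = list(
    list(motif = "AAAAAAAAAAAG", at = 40)), seed = seed)
  f3 <- file.path(dir, "transcript_planted.fasta")
  write_fasta(list(tx), f3)
  mc <- make_mini_complex(c(2L, 1L, 2L), seed = seed)
  f4 <- file.path(dir, "mini_complex_212.pdb")
  write_pdb(mc$model, f4)
  invisible(c(f1, f2, f3, f4))
}
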