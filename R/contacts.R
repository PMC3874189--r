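# Contact detectors implementing the adenosine recognition grammar:
# zinc coordination sites, base/aromatic stacking, the specificity H-bond
# categories, solvent bridges, cation-pi geometry, and Watson-Crick vs
# Hoogsteen edge orientation relative to the Zn cluster.

#' Find zinc coordination sites
#'
#' One site per ZN atom. Ligands are cysteine SG within the sulfur cutoff
#' and histidine ND1/NE2 within the nitrogen cutoff, sorted by distance.
#' A ZN with no ligand in range is kept and flagged: it is a real atom but
#' not a structural CCCH site.
#'
#' @param model [structure_model()].
#' @param cutoff list with `d_s` and `d_n` (angstrom); default 2.6 / 2.5.
#' @return list of sites, each a list with `zn` (one-row atom table),
#'   `ligands` (atom table with a `distance` column) and `flagged`.
#' @export
find_zn_sites <- function(model, cutoff = default_config()$zn) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  zn_idx <- which(at$elem == "ZN" | (at$resid == "ZN" & at$elety == "ZN"))
  lig_idx <- which((at$elety == "SG" & at$resid == "CYS") |
                   (at$elety %in% c("ND1", "NE2") & at$resid == "HIS"))
  sites <- list()
  for (zi in zn_idx) {
    zn_xyz <- as.numeric(at[zi, c("x", "y", "z")])
    keep <- integer(); dd <- numeric()
    for (li in lig_idx) {
      d <- dist3(zn_xyz, as.numeric(at[li, c("x", "y", "z")]))
      lim <- if (at$elety[li] == "SG") cutoff$d_s else cutoff$d_n
      if (d <= lim) { keep <- c(keep, li); dd <- c(dd, d) }
    }
    ord <- order(dd)
    ligands <- at[keep[ord], , drop = FALSE]
    ligands$distance <- dd[ord]
    sites[[length(sites) + 1L]] <- list(
      zn = at[zi, , drop = FALSE], zn_index = zi,
      ligands = ligands, ligand_index = keep[ord],
      flagged = length(keep) == 0L)
  }
  sites
}

# SG atom indices that coordinate any Zn site
zn_cys_sg_indices <- function(sites) {
  unlist(lapply(sites, function(s) {
    if (!nrow(s$ligands)) return(integer())
    s$ligand_index[s$ligands$elety == "SG"]
  }))
}

#' Detect base/aromatic stacking contacts
#'
#' Pairs each purine six-membered ring with each aromatic side-chain ring
#' (Phe, Tyr, His, both Trp rings) and accepts a contact when the centroid
#' distance, interplanar angle and lateral offset all pass the thresholds.
#' The lateral offset is measured against both ring normals and the smaller
#' value taken, making the test symmetric in ring order.
#'
#' @param model [structure_model()].
#' @param params list with `d_max`, `angle_max` (degrees), `offset_max`.
#' @return data frame, one row per contact: base and side-chain residue
#'   identifiers, `centroid_distance`, `interplanar_angle`,
#'   `lateral_offset`.
#' @export
detect_stacking <- function(model, params = default_config()$stacking) {
  rings <- extract_rings(model)
  bases <- Filter(function(r) r$kind == "base", rings)
  arom <- Filter(function(r) r$kind == "sidechain", rings)
  out <- list()
  for (b in bases) for (a in arom) {
    d <- dist3(b$centroid, a$centroid)
    if (d > params$d_max) next
    cosang <- abs(sum(b$normal * a$normal))
    ang <- acos(max(-1, min(1, cosang))) * 180 / pi
    if (ang > params$angle_max) next
    v <- a$centroid - b$centroid
    off_b <- vnorm(v - sum(v * b$normal) * b$normal)
    off_a <- vnorm(v - sum(v * a$normal) * a$normal)
    off <- min(off_b, off_a)
    if (off > params$offset_max) next
    out[[length(out) + 1L]] <- data.frame(
      base_chain = b$chain, base_resno = b$resno, base_resid = b$resid,
      sc_chain = a$chain, sc_resno = a$resno, sc_resid = a$resid,
      sc_ring = a$ring, centroid_distance = d, interplanar_angle = ang,
      lateral_offset = off, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_stacking_df())
  df <- do.call(rbind, out)
  df[order(df$base_chain, df$base_resno, df$sc_chain, df$sc_resno), ,
     drop = FALSE]
}

empty_stacking_df <- function() {
  data.frame(base_chain = character(), base_resno = integer(),
             base_resid = character(), sc_chain = character(),
             sc_resno = integer(), sc_resid = character(),
             sc_ring = character(), centroid_distance = numeric(),
             interplanar_angle = numeric(), lateral_offset = numeric(),
             stringsAsFactors = FALSE)
}

# donor/acceptor inventory used by detect_hbonds: heavy atoms only.
# Donors: adenine N6 (antecedent C6), protein backbone N (antecedent CA).
# Acceptors: adenine N1/N7, Zn-cysteine SG, protein backbone O.
hbond_inventory <- function(model, sites) {
  at <- model$atoms
  sg_zn <- zn_cys_sg_indices(sites)
  donors <- data.frame(
    index = c(which(at$polymer == "rna" & at$elety == "N6"),
              which(at$polymer == "protein" & at$elety == "N")),
    stringsAsFactors = FALSE)
  donors$side <- ifelse(at$polymer[donors$index] == "rna", "rna", "protein")
  donors$kind <- ifelse(donors$side == "rna", "N6", "backbone_N")
  acc_idx <- c(which(at$polymer == "rna" & at$elety %in% c("N1", "N7")),
               which(at$polymer == "protein" & at$elety == "O"),
               which(at$elety == "SG" & at$resid == "CYS"))
  acceptors <- data.frame(index = acc_idx, stringsAsFactors = FALSE)
  acceptors$side <- ifelse(at$polymer[acc_idx] == "rna", "rna", "protein")
  acceptors$kind <- ifelse(at$elety[acc_idx] == "SG",
                           ifelse(acc_idx %in% sg_zn, "SG_ZnCys", "SG_free"),
                    ifelse(at$elety[acc_idx] == "O", "backbone_O",
                           at$elety[acc_idx]))
  list(donors = donors, acceptors = acceptors)
}

donor_antecedent <- function(model, donor_row) {
  at <- model$atoms
  if (donor_row$kind == "N6") ante <- "C6" else ante <- "CA"
  residue_atom(model, at$chain[donor_row$index], at$resno[donor_row$index],
               ante)
}

#' Detect specificity hydrogen bonds between protein and RNA
#'
#' Heavy-atom criterion (the crystal has no hydrogens): donor-acceptor
#' distance within the cutoff (a longer cutoff applies when sulfur is the
#' acceptor) plus an acceptor-donor-antecedent angle of at least
#' `angle_min` degrees as a hydrogen-free directionality surrogate; the
#' angle test is applied only when the donor's antecedent atom (C6 for
#' adenine N6, CA for a backbone amide) is present in the model.
#'
#' Categories follow the recognition grammar: `N6->SG_ZnCys` requires the
#' cysteine sulfur to be a ligand of a detected Zn site;
#' `backboneNH->N1` and `backboneNH->N7` are the amide bonds that read the
#' Watson-Crick or Hoogsteen edge; `N6->backboneCO` is the carbonyl
#' variant; any other in-range protein/RNA donor-acceptor pair is kept as
#' `other`.
#'
#' @param model [structure_model()].
#' @param params list with `d_max`, `d_max_s`, `angle_min`.
#' @param sites Zn sites from [find_zn_sites()] (computed if missing).
#' @return data frame, one row per bond: donor/acceptor identifiers,
#'   `distance`, `angle` (NA when the antecedent is absent), `category`.
#' @export
detect_hbonds <- function(model, params = default_config()$hbond,
                          sites = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(sites)) sites <- find_zn_sites(model)
  inv <- hbond_inventory(model, sites)
  at <- model$atoms
  out <- list()
  for (di in seq_len(nrow(inv$donors))) {
    d <- inv$donors[di, ]
    dxyz <- as.numeric(at[d$index, c("x", "y", "z")])
    for (ai in seq_len(nrow(inv$acceptors))) {
      a <- inv$acceptors[ai, ]
      if (d$side == a$side) next   # bonds must span protein <-> RNA
      axyz <- as.numeric(at[a$index, c("x", "y", "z")])
      lim <- if (a$kind %in% c("SG_ZnCys", "SG_free"))
        params$d_max_s else params$d_max
      dd <- dist3(dxyz, axyz)
      if (dd > lim) next
      ante <- donor_antecedent(model, d)
      ang <- NA_real_
      if (!is.null(ante)) {
        ang <- angle_deg(axyz, dxyz,
                         as.numeric(ante[1, c("x", "y", "z")]))
        if (ang < params$angle_min) next
      }
      category <- hbond_category(d$kind, a$kind)
      out[[length(out) + 1L]] <- data.frame(
        donor_chain = at$chain[d$index], donor_resno = at$resno[d$index],
        donor_resid = at$resid[d$index], donor_atom = at$elety[d$index],
        acceptor_chain = at$chain[a$index],
        acceptor_resno = at$resno[a$index],
        acceptor_resid = at$resid[a$index],
        acceptor_atom = at$elety[a$index],
        distance = dd, angle = ang, category = category,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_hbond_df())
  df <- do.call(rbind, out)
  df[order(df$donor_chain, df$donor_resno, df$acceptor_chain,
           df$acceptor_resno, df$acceptor_atom), , drop = FALSE]
}

hbond_category <- function(donor_kind, acceptor_kind) {
  if (donor_kind == "N6" && acceptor_kind == "SG_ZnCys")
    return("N6->SG_ZnCys")
  if (donor_kind == "backbone_N" && acceptor_kind == "N1")
    return("backboneNH->N1")
  if (donor_kind == "backbone_N" && acceptor_kind == "N7")
    return("backboneNH->N7")
  if (donor_kind == "N6" && acceptor_kind == "backbone_O")
    return("N6->backboneCO")
  "other"
}

empty_hbond_df <- function() {
  data.frame(donor_chain = character(), donor_resno = integer(),
             donor_resid = character(), donor_atom = character(),
             acceptor_chain = character(), acceptor_resno = integer(),
             acceptor_resid = character(), acceptor_atom = character(),
             distance = numeric(), angle = numeric(),
             category = character(), stringsAsFactors = FALSE)
}

#' Detect solvent-mediated bridges
#'
#' A water oxygen within the H-bond cutoff of two polar heavy atoms (N or O)
#' belonging to different non-water residues bridges them; every such pair
#' of partners is reported.
#'
#' @param model [structure_model()].
#' @param cutoff distance cutoff in angstrom (default the H-bond `d_max`).
#' @return data frame: water identifier, both partners, both distances.
#' @export
detect_water_bridges <- function(model,
                                 cutoff = default_config()$hbond$d_max) {
  at <- model$atoms
  waters <- which(at$polymer == "water" & at$elem == "O")
  polar <- which(at$polymer != "water" & at$elem %in% c("N", "O"))
  out <- list()
  for (wi in waters) {
    wxyz <- as.numeric(at[wi, c("x", "y", "z")])
    near <- polar[vapply(polar, function(p)
      dist3(wxyz, as.numeric(at[p, c("x", "y", "z")])) <= cutoff,
      logical(1))]
    if (length(near) < 2L) next
    for (i in seq_len(length(near) - 1L)) for (j in (i + 1L):length(near)) {
      pa <- near[i]; pb <- near[j]
      same_res <- at$chain[pa] == at$chain[pb] &&
        at$resno[pa] == at$resno[pb]
      if (same_res) next
      out[[length(out) + 1L]] <- data.frame(
        water_chain = at$chain[wi], water_resno = at$resno[wi],
        a_chain = at$chain[pa], a_resno = at$resno[pa],
        a_resid = at$resid[pa], a_atom = at$elety[pa],
        b_chain = at$chain[pb], b_resno = at$resno[pb],
        b_resid = at$resid[pb], b_atom = at$elety[pb],
        dist_a = dist3(wxyz, as.numeric(at[pa, c("x", "y", "z")])),
        dist_b = dist3(wxyz, as.numeric(at[pb, c("x", "y", "z")])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(water_chain = character(), water_resno = integer(),
                      a_chain = character(), a_resno = integer(),
                      a_resid = character(), a_atom = character(),
                      b_chain = character(), b_resno = integer(),
                      b_resid = character(), b_atom = character(),
                      dist_a = numeric(), dist_b = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Assess cation-pi geometry between basic side chains and base rings
#'
#' Cation reference points are Lys NZ and Arg CZ. A contact passes when the
#' cation lies within `d_max` of the base-ring centroid and the axial angle
#' (between the ring normal and the centroid-to-cation vector, folded to
#' 0..90 degrees) is at most `axial_max` -- i.e. the charge sits over the
#' ring face, not in its plane. Failing geometries within 1.5 x `d_max` are
#' retained with `passes = FALSE` so that near-misses can be reported.
#'
#' @param model [structure_model()].
#' @param params list with `d_max`, `axial_max`.
#' @return data frame: cation identifier, ring identifier, `distance`,
#'   `axial_angle`, `passes`.
#' @export
detect_cation_pi <- function(model, params = default_config()$cation_pi) {
  at <- model$atoms
  cat_idx <- which((at$resid == "LYS" & at$elety == "NZ") |
                   (at$resid == "ARG" & at$elety == "CZ"))
  rings <- Filter(function(r) r$kind == "base",
                  extract_rings(model, kinds = "base"))
  out <- list()
  for (ci in cat_idx) {
    cxyz <- as.numeric(at[ci, c("x", "y", "z")])
    for (r in rings) {
      v <- cxyz - r$centroid
      d <- vnorm(v)
      if (d > 1.5 * params$d_max) next
      ax <- acos(max(-1, min(1, abs(sum(unit(v) * r$normal))))) * 180 / pi
      out[[length(out) + 1L]] <- data.frame(
        cation_chain = at$chain[ci], cation_resno = at$resno[ci],
        cation_resid = at$resid[ci], cation_atom = at$elety[ci],
        base_chain = r$chain, base_resno = r$resno, base_resid = r$resid,
        distance = d, axial_angle = ax,
        passes = d <= params$d_max && ax <= params$axial_max,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cation_chain = character(), cation_resno = integer(),
                      cation_resid = character(), cation_atom = character(),
                      base_chain = character(), base_resno = integer(),
                      base_resid = character(), distance = numeric(),
                      axial_angle = numeric(), passes = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify which purine edge faces a zinc site
#'
#' A purine reads into the binding pocket either Watson-Crick edge first
#' (N1 side) or Hoogsteen edge first (N7 side). The call compares the
#' N1-Zn and N7-Zn distances: Watson-Crick when N1 is closer by more than
#' the margin, Hoogsteen when N7 is, indeterminate within the margin.
#'
#' @param model [structure_model()].
#' @param chain,resno identify the purine residue.
#' @param zn_site one site from [find_zn_sites()].
#' @param margin distance margin in angstrom (default 0.5).
#' @return `"WatsonCrick"`, `"Hoogsteen"` or `"indeterminate"`.
#' @export
classify_base_edge <- function(model, chain, resno, zn_site,
                               margin = default_config()$edge_margin) {
  n1 <- residue_atom(model, chain, resno, "N1")
  n7 <- residue_atom(model, chain, resno, "N7")
  if (is.null(n1) || is.null(n7))
    stop("residue ", chain, resno, " lacks N1/N7 atoms", call. = FALSE)
  zn <- as.numeric(zn_site$zn[1, c("x", "y", "z")])
  d1 <- dist3(as.numeric(n1[1, c("x", "y", "z")]), zn)
  d7 <- dist3(as.numeric(n7[1, c("x", "y", "z")]), zn)
  if (d1 < d7 - margin) "WatsonCrick"
  else if (d7 < d1 - margin) "Hoogsteen"
  else "indeterminate"
}
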