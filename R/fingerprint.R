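# Per-finger interaction fingerprint: runs every detector, assigns each
# contacted adenosine to a finger, classifies its edge and sums the buried
# interface area.

#' Build a protein-RNA interaction fingerprint
#'
#' Runs the Zn-site, stacking, H-bond, water-bridge and cation-pi
#' detectors, then assigns every adenosine that has at least one stacking
#' or H-bond contact to a finger: primarily the finger whose span contains
#' the stacking aromatic residue, otherwise the finger with the most
#' contacting protein atoms. Edge orientation is classified against the
#' nearest Zn site. Buried area is computed between the protein chains and
#' the interface RNA nucleotides (those with any atom within
#' `buried_contact_cutoff` of the protein).
#'
#' @param model [structure_model()].
#' @param fingers data frame with columns `finger` (label), `chain`, `c1`,
#'   `h` giving each finger's chain and author residue-number span, as
#'   produced by [detect_ccch_fingers()] plus a chain column.
#' @param config full parameter list (default [default_config()]).
#' @param compute_area logical; set `FALSE` to skip the (slower) buried
#'   area.
#' @return list of class `interaction_fingerprint`: `records` (one row per
#'   bound adenosine: chain, resno, assigned finger, edge, numbers of each
#'   contact type), `bases_per_finger` (named integer vector),
#'   `buried_area`, `zn_sites`, and the raw contact tables.
#' @export
build_fingerprint <- function(model, fingers, config = default_config(),
                              compute_area = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  sites <- find_zn_sites(model, config$zn)
  stacks <- detect_stacking(model, config$stacking)
  hbonds <- detect_hbonds(model, config$hbond, sites = sites)
  bridges <- detect_water_bridges(model, config$hbond$d_max)
  cpi <- detect_cation_pi(model, config$cation_pi)

  at <- model$atoms
  ade <- unique(at[at$polymer == "rna" &
                     at$resid %in% c("A", "RA", "ADE"),
                   c("chain", "resno")])
  records <- list()
  for (r in seq_len(nrow(ade))) {
    ch <- ade$chain[r]; rn <- ade$resno[r]
    st <- stacks[stacks$base_chain == ch & stacks$base_resno == rn, ,
                 drop = FALSE]
    hb <- hbonds[(hbonds$donor_chain == ch & hbonds$donor_resno == rn) |
                 (hbonds$acceptor_chain == ch &
                    hbonds$acceptor_resno == rn), , drop = FALSE]
    if (!nrow(st) && !nrow(hb)) next
    fi <- assign_finger(fingers, st, hb)
    edge <- edge_for_base(model, ch, rn, sites, config$edge_margin)
    n_cpi <- if (nrow(cpi))
      sum(cpi$base_chain == ch & cpi$base_resno == rn & cpi$passes)
    else 0L
    records[[length(records) + 1L]] <- data.frame(
      chain = ch, resno = rn, finger = fi, edge = edge,
      n_stacking = nrow(st), n_hbonds = nrow(hb),
      n_cation_pi = n_cpi, stringsAsFactors = FALSE)
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(chain = character(), resno = integer(), finger = character(),
               edge = character(), n_stacking = integer(),
               n_hbonds = integer(), n_cation_pi = integer(),
               stringsAsFactors = FALSE)

  counts <- integer(nrow(fingers))
  names(counts) <- as.character(fingers$finger)
  if (nrow(records)) {
    tab <- table(records$finger)
    counts[names(tab)] <- as.integer(tab)
  }

  buried <- NA_real_
  if (compute_area && nrow(records)) {
    prot <- select_atoms(model, polymer = "protein")
    rna_all <- select_atoms(model, polymer = "rna")
    if (length(prot) && length(rna_all)) {
      iface <- interface_nucleotides(model, prot, rna_all,
                                     config$buried_contact_cutoff)
      if (length(iface)) {
        buried <- compute_buried_area(model, prot, iface,
                                      probe = config$sasa$probe,
                                      n_points = config$sasa$n_points,
                                      radii = config$sasa$radii)
      } else buried <- 0
    }
  } else if (compute_area) buried <- 0

  structure(list(records = records, bases_per_finger = counts,
                 buried_area = buried, zn_sites = sites,
                 stacking = stacks, hbonds = hbonds,
                 water_bridges = bridges, cation_pi = cpi),
            class = "interaction_fingerprint")
}

# finger whose span holds the stacking aromatic; fallback: most contact
# atoms; NA when nothing matches a finger span
assign_finger <- function(fingers, st, hb) {
  hit_finger <- function(chain, resno) {
    m <- which(fingers$chain == chain & fingers$c1 <= resno &
                 fingers$h >= resno)
    if (length(m)) as.character(fingers$finger[m[1L]]) else NA_character_
  }
  if (nrow(st)) {
    for (k in seq_len(nrow(st))) {
      f <- hit_finger(st$sc_chain[k], st$sc_resno[k])
      if (!is.na(f)) return(f)
    }
  }
  # fallback: count protein-side contact atoms per finger
  votes <- character()
  if (nrow(hb)) {
    prot_side <- ifelse(hb$donor_atom == "N6",
                        paste(hb$acceptor_chain, hb$acceptor_resno),
                        paste(hb$donor_chain, hb$donor_resno))
    for (p in prot_side) {
      parts <- strsplit(p, " ")[[1L]]
      f <- hit_finger(parts[1L], as.integer(parts[2L]))
      if (!is.na(f)) votes <- c(votes, f)
    }
  }
  if (length(votes)) names(sort(table(votes), decreasing = TRUE))[1L]
  else NA_character_
}

edge_for_base <- function(model, chain, resno, sites, margin) {
  if (!length(sites)) return("indeterminate")
  n9 <- residue_atom(model, chain, resno, "N9")
  ref <- if (!is.null(n9)) n9 else residue_atom(model, chain, resno, "C4")
  if (is.null(ref)) return("indeterminate")
  rxyz <- as.numeric(ref[1, c("x", "y", "z")])
  dd <- vapply(sites, function(s)
    dist3(rxyz, as.numeric(s$zn[1, c("x", "y", "z")])), numeric(1))
  classify_base_edge(model, chain, resno, sites[[which.min(dd)]], margin)
}

interface_nucleotides <- function(model, prot_idx, rna_idx, cutoff) {
  at <- model$atoms
  pxyz <- atom_xyz(model, prot_idx)
  res <- unique(at[rna_idx, c("chain", "resno")])
  keep <- integer()
  for (r in seq_len(nrow(res))) {
    ridx <- rna_idx[at$chain[rna_idx] == res$chain[r] &
                      at$resno[rna_idx] == res$resno[r]]
    rxyz <- atom_xyz(model, ridx)
    mind <- min(vapply(seq_len(nrow(rxyz)), function(i)
      min(sqrt((pxyz[, 1] - rxyz[i, 1])^2 + (pxyz[, 2] - rxyz[i, 2])^2 +
                 (pxyz[, 3] - rxyz[i, 3])^2)), numeric(1)))
    if (mind <= cutoff) keep <- c(keep, ridx)
  }
  keep
}

#' @export
print.interaction_fingerprint <- function(x, ...) {
  cat("<interaction_fingerprint> ", nrow(x$records), " bound bases; ",
      "per finger: ",
      paste(sprintf("%s=%d", names(x$bases_per_finger),
                    x$bases_per_finger), collapse = ", "),
      "; buried area ",
      if (is.na(x$buried_area)) "not computed" else
        paste0(format(x$buried_area, digits = 5), " A^2"),
      "; ", length(x$zn_sites), " Zn site(s)\n", sep = "")
  invisible(x)
}
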