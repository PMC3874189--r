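# Small vector-geometry helpers and ring extraction shared by the contact
# detectors.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector", call. = FALSE)
  v / n
}

# angle at vertex b of the path a-b-c, degrees
angle_deg <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

dist3 <- function(a, b) vnorm(a - b)

# ring atom-name tables: six-membered base ring for purines; aromatic
# side-chain rings (Trp contributes both of its rings)
RING_DEFS <- list(
  base_six = list(resid = c("A", "G", "RA", "RG", "ADE", "GUA"),
                  atoms = c("N1", "C2", "N3", "C4", "C5", "C6")),
  phe = list(resid = "PHE",
             atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  tyr = list(resid = "TYR",
             atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  his = list(resid = "HIS", atoms = c("CG", "ND1", "CD2", "CE1", "NE2")),
  trp_five = list(resid = "TRP",
                  atoms = c("CG", "CD1", "NE1", "CE2", "CD2")),
  trp_six = list(resid = "TRP",
                 atoms = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

# plane fit: centroid + unit normal (least-squares via SVD)
ring_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  centred <- sweep(xyz, 2L, ctr)
  sv <- svd(centred)
  list(centroid = ctr, normal = unit(sv$v[, 3L]))
}

# all rings in the model: data list with kind ("base"/"sidechain"),
# chain, resno, resid, ring name, centroid, normal
extract_rings <- function(model, kinds = c("base", "sidechain")) {
  at <- model$atoms
  rings <- list()
  res_key <- unique(at[, c("chain", "resno", "resid")])
  for (r in seq_len(nrow(res_key))) {
    resid <- res_key$resid[r]
    for (nm in names(RING_DEFS)) {
      def <- RING_DEFS[[nm]]
      if (!resid %in% def$resid) next
      kind <- if (nm == "base_six") "base" else "sidechain"
      if (!kind %in% kinds) next
      sel <- at$chain == res_key$chain[r] & at$resno == res_key$resno[r] &
        at$resid == resid & at$elety %in% def$atoms
      if (sum(sel) < length(def$atoms)) {
        # warn only for a genuinely truncated ring; residues whose side
        # chain simply is not modelled are skipped silently
        if (sum(sel) >= 3L)
          warning("residue ", resid, " ", res_key$chain[r],
                  res_key$resno[r], " missing ring atoms; skipped",
                  call. = FALSE)
        next
      }
      pl <- ring_plane(as.matrix(at[sel, c("x", "y", "z")]))
      rings[[length(rings) + 1L]] <- list(
        kind = kind, chain = res_key$chain[r], resno = res_key$resno[r],
        resid = resid, ring = nm, centroid = pl$centroid,
        normal = pl$normal)
    }
  }
  rings
}
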