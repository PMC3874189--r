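# FASTA input/output and report writers. Reports are UTF-8 TSV with a
# header row, or JSON mirroring the same schema; every report carries the
# tool version and the MD5 hash of the effective configuration.

#' Read a multi-record FASTA file
#'
#' @param path FASTA file.
#' @param type `"protein"` (returns [protein_sequence()] objects),
#'   `"rna"` ([rna_seq()]) or `"raw"` (named character vector).
#' @return list of sequence objects (or named character for `"raw"`).
#'   An empty file yields an empty list; duplicate ids are kept with a
#'   warning.
#' @export
read_fasta <- function(path, type = c("protein", "rna", "raw")) {
  type <- match.arg(type)
  if (!file.size(path)) return(if (type == "raw") character() else list())
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(trimws(first), ">"))
    stop("malformed FASTA header at line 1 of ", path, call. = FALSE)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             seqonly = FALSE)
  ids <- unname(vapply(recs, function(r) attr(r, "name"), character(1)))
  if (anyDuplicated(ids))
    warning("duplicate FASTA ids in ", path, "; all records kept",
            call. = FALSE)
  seqs <- unname(vapply(recs, function(r) toupper(as.character(r)[1L]),
                        character(1)))
  if (type == "raw") return(stats::setNames(seqs, ids))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    out[[i]] <- if (type == "protein") protein_sequence(ids[i], seqs[i])
    else rna_seq(ids[i], seqs[i])
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs list of [protein_sequence()] / [rna_seq()] objects, or a
#'   named character vector.
#' @param path output file; lines wrap at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    ids <- names(seqs)
    strings <- unname(seqs)
  } else {
    ids <- vapply(seqs, function(s) s$id, character(1))
    strings <- vapply(seqs, function(s)
      if (inherits(s, "rna_seq")) s$bases else s$residues, character(1))
  }
  seqinr::write.fasta(strsplit(strings, ""), names = ids,
                      file.out = path, nbchar = 60)
  invisible(path)
}

report_meta <- function(config) {
  list(tool = "polyAcode", version = pkg_version_string(),
       config_hash = config_hash(config))
}

#' Write a finger-code report
#'
#' One row per detected finger: positions, loops, code features, the
#' stoichiometry call and its rationale. TSV and/or JSON depending on the
#' extension(s) given.
#'
#' @param calls `znf_calls` data frame from [predict_stoichiometry()] or
#'   [call_finger_array()].
#' @param path output path; `.tsv` or `.json`.
#' @param config effective configuration (stamped into the report).
#' @return `path`, invisibly.
#' @export
write_finger_report <- function(calls, path, config = default_config()) {
  cols <- c("parent_id", "c1", "c2", "c3", "h", "loop1", "loop2", "loop3",
            "res_c1p1", "res_c1p2", "res_c3p2", "basic_after_c1",
            "aromatic_c1p2", "aromatic_c3p2", "exception_leu_his",
            "n_adenosines", "rationale")
  tab <- as.data.frame(calls)[, intersect(cols, names(calls)),
                              drop = FALSE]
  if (grepl("\\.json$", path)) {
    payload <- c(report_meta(config),
                 list(fingers = tab,
                      array_capacity = if (nrow(tab))
                        predict_array_capacity(calls) else 0L))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    write_tsv_with_meta(tab, path, config)
  }
  invisible(path)
}

write_tsv_with_meta <- function(tab, path, config) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  meta <- report_meta(config)
  writeLines(sprintf("# %s %s config=%s", meta$tool, meta$version,
                     meta$config_hash), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a contact table
#'
#' One contact per row across all categories of an interaction
#' fingerprint: type, partners and the governing geometry.
#'
#' @param fp [build_fingerprint()] result.
#' @param path output TSV.
#' @param config effective configuration.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(fp, path, config = default_config()) {
  stopifnot(inherits(fp, "interaction_fingerprint"))
  rows <- list()
  st <- fp$stacking
  if (nrow(st))
    rows[[length(rows) + 1L]] <- data.frame(
      type = "stacking",
      partner_a = sprintf("%s/%s%d", st$base_chain, st$base_resid,
                          st$base_resno),
      partner_b = sprintf("%s/%s%d", st$sc_chain, st$sc_resid,
                          st$sc_resno),
      category = st$sc_ring, distance = st$centroid_distance,
      angle = st$interplanar_angle, stringsAsFactors = FALSE)
  hb <- fp$hbonds
  if (nrow(hb))
    rows[[length(rows) + 1L]] <- data.frame(
      type = "hbond",
      partner_a = sprintf("%s/%s%d:%s", hb$donor_chain, hb$donor_resid,
                          hb$donor_resno, hb$donor_atom),
      partner_b = sprintf("%s/%s%d:%s", hb$acceptor_chain,
                          hb$acceptor_resid, hb$acceptor_resno,
                          hb$acceptor_atom),
      category = hb$category, distance = hb$distance, angle = hb$angle,
      stringsAsFactors = FALSE)
  wb <- fp$water_bridges
  if (nrow(wb))
    rows[[length(rows) + 1L]] <- data.frame(
      type = "water_bridge",
      partner_a = sprintf("%s/%s%d:%s", wb$a_chain, wb$a_resid,
                          wb$a_resno, wb$a_atom),
      partner_b = sprintf("%s/%s%d:%s", wb$b_chain, wb$b_resid,
                          wb$b_resno, wb$b_atom),
      category = sprintf("via %s%d", wb$water_chain, wb$water_resno),
      distance = (wb$dist_a + wb$dist_b) / 2, angle = NA_real_,
      stringsAsFactors = FALSE)
  cp <- fp$cation_pi
  if (nrow(cp))
    rows[[length(rows) + 1L]] <- data.frame(
      type = "cation_pi",
      partner_a = sprintf("%s/%s%d:%s", cp$cation_chain, cp$cation_resid,
                          cp$cation_resno, cp$cation_atom),
      partner_b = sprintf("%s/%s%d", cp$base_chain, cp$base_resid,
                          cp$base_resno),
      category = ifelse(cp$passes, "pass", "fail"),
      distance = cp$distance, angle = cp$axial_angle,
      stringsAsFactors = FALSE)
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), partner_a = character(),
               partner_b = character(), category = character(),
               distance = numeric(), angle = numeric(),
               stringsAsFactors = FALSE)
  write_tsv_with_meta(tab, path, config)
}

#' Serialise an interaction fingerprint to JSON
#'
#' @param fp [build_fingerprint()] result.
#' @param path output file; when `NULL` the JSON string is returned.
#' @param config effective configuration.
#' @return path (invisibly) or JSON string.
#' @export
fingerprint_to_json <- function(fp, path = NULL,
                                config = default_config()) {
  stopifnot(inherits(fp, "interaction_fingerprint"))
  payload <- c(report_meta(config), list(
    bases_per_finger = as.list(fp$bases_per_finger),
    buried_area = fp$buried_area,
    n_zn_sites = length(fp$zn_sites),
    records = fp$records,
    n_stacking = nrow(fp$stacking),
    n_hbonds = nrow(fp$hbonds),
    n_water_bridges = nrow(fp$water_bridges),
    n_cation_pi_pass = if (nrow(fp$cation_pi))
      sum(fp$cation_pi$passes) else 0L))
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write motif hits as BED-like TSV
#'
#' 0-based half-open intervals: `seq_id`, `start`, `end`, `score`, `type`.
#'
#' @param hits `motif_hits` data frame.
#' @param path output TSV.
#' @param config effective configuration.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, config = default_config()) {
  tab <- as.data.frame(hits)[, c("seq_id", "start", "end", "score",
                                 "type"), drop = FALSE]
  write_tsv_with_meta(tab, path, config)
}
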