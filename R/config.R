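# Run configuration: every geometric threshold and scanner parameter in one
# place, with defaults documented on default_config(). Configs round-trip to
# a flat key=value file.

#' Default run configuration
#'
#' Returns the full set of tunable parameters with their defaults. All
#' detectors accept either the whole config or the relevant sub-list, so a
#' single edited config reproducibly drives every stage.
#'
#' Defaults:
#' \describe{
#'   \item{spacing}{CCCH loop-length bounds `C-x(4..8)-C-x(4..6)-C-x(3)-H`,
#'     bracketing the Nab2- and TIS11d-class fingers.}
#'   \item{aromatic / basic}{residue code sets \{F,Y,W\} and \{K,R\}; W is
#'     included as chemically equivalent to F/Y.}
#'   \item{leu_his_exception}{`TRUE`: Leu directly after the first Cys
#'     together with His two after the third Cys counts as a two-adenosine
#'     finger (the finger-1-style exception).}
#'   \item{hbond}{heavy-atom donor-acceptor cutoff 3.5 angstrom (3.9 when
#'     sulfur is the acceptor), acceptor-donor-antecedent angle >= 90
#'     degrees as a hydrogen-free surrogate.}
#'   \item{stacking}{ring-centroid distance <= 4.5 angstrom, interplanar
#'     angle <= 30 degrees, lateral offset <= 2.5 angstrom.}
#'   \item{cation_pi}{cation point (Lys NZ / Arg CZ) within 6.0 angstrom of
#'     the ring centroid and axial angle <= 45 degrees.}
#'   \item{zn}{ligand cutoffs 2.6 angstrom (S) / 2.5 angstrom (N).}
#'   \item{edge_margin}{0.5 angstrom margin between d(N1,Zn) and d(N7,Zn)
#'     for Watson-Crick vs Hoogsteen calls; within the margin the edge is
#'     indeterminate.}
#'   \item{sasa}{probe 1.4 angstrom, 960 golden-spiral points, van der
#'     Waals radii C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, Zn 1.39,
#'     Mg 1.73 angstrom.}
#'   \item{buried_contact_cutoff}{4.5 angstrom: an RNA nucleotide belongs
#'     to the interface group if any atom lies within this of the protein.}
#'   \item{footprint}{window span 8 nt for a three-finger array.}
#' }
#'
#' @return nested named list of parameters.
#' @export
default_config <- function() {
  list(
    spacing = list(loop1 = c(4L, 8L), loop2 = c(4L, 6L), loop3 = c(3L, 3L)),
    aromatic = c("F", "Y", "W"),
    basic = c("K", "R"),
    leu_his_exception = TRUE,
    hbond = list(d_max = 3.5, d_max_s = 3.9, angle_min = 90),
    stacking = list(d_max = 4.5, angle_max = 30, offset_max = 2.5),
    cation_pi = list(d_max = 6.0, axial_max = 45),
    zn = list(d_s = 2.6, d_n = 2.5),
    edge_margin = 0.5,
    sasa = list(
      probe = 1.4, n_points = 960L,
      radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                ZN = 1.39, MG = 1.73, H = 1.20)),
    buried_contact_cutoff = 4.5,
    footprint = list(span = 8L),
    seed = 1L,
    verbosity = 1L
  )
}

flatten_config <- function(x, prefix = character()) {
  out <- list()
  for (nm in names(x)) {
    key <- paste(c(prefix, nm), collapse = ".")
    v <- x[[nm]]
    if (is.list(v)) {
      out <- c(out, flatten_config(v, c(prefix, nm)))
    } else {
      out[[key]] <- v
    }
  }
  out
}

fmt_value <- function(v) {
  if (is.numeric(v)) {
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
  } else if (is.logical(v)) {
    s <- ifelse(v, "TRUE", "FALSE")
  } else {
    s <- as.character(v)
  }
  if (!is.null(names(v)) && length(names(v)))
    s <- paste0(names(v), ":", s)
  paste(s, collapse = ",")
}

#' Write a configuration to a flat key=value file
#'
#' Nested names are dotted (`hbond.d_max=3.5`); vectors are comma-joined,
#' named vectors as `name:value` pairs. [read_config()] inverts this
#' losslessly against the [default_config()] template.
#'
#' @param config nested list as from [default_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  flat <- flatten_config(config)
  lines <- vapply(names(flat),
                  function(k) paste0(k, "=", fmt_value(flat[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' Unknown keys are an error; missing keys keep their defaults, so a config
#' file may state only overrides. Value types are taken from the template.
#'
#' @param path file written by [write_config()] (or hand-edited).
#' @param template config supplying structure and types; default
#'   [default_config()].
#' @return nested config list.
#' @export
read_config <- function(path, template = default_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  flat_tpl <- flatten_config(template)
  cfg <- template
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (no '='): ", ln, call. = FALSE)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!key %in% names(flat_tpl))
      stop("unknown config key: ", key, call. = FALSE)
    tpl <- flat_tpl[[key]]
    parts <- strsplit(val, ",", fixed = TRUE)[[1L]]
    if (any(grepl(":", parts, fixed = TRUE))) {
      kv <- strsplit(parts, ":", fixed = TRUE)
      parsed <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
      names(parsed) <- vapply(kv, `[`, character(1), 1)
    } else if (is.numeric(tpl)) {
      parsed <- as.numeric(parts)
      if (is.integer(tpl)) parsed <- as.integer(parsed)
    } else if (is.logical(tpl)) {
      parsed <- as.logical(parts)
    } else {
      parsed <- parts
    }
    # assign into the nested list by dotted path
    pth <- strsplit(key, ".", fixed = TRUE)[[1L]]
    cfg <- modify_at_path(cfg, pth, parsed)
  }
  cfg
}

modify_at_path <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
    return(x)
  }
  x[[path[1L]]] <- modify_at_path(x[[path[1L]]], path[-1L], value)
  x
}

#' Hash of the effective configuration
#'
#' MD5 of the canonical flat rendering, used to stamp reports so identical
#' inputs and config produce identical, attributable output.
#'
#' @param config config list.
#' @return character MD5 hash.
#' @export
config_hash <- function(config = default_config()) {
  tf <- tempfile(fileext = ".cfg")
  on.exit(unlink(tf), add = TRUE)
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

pkg_version_string <- function() {
  as.character(utils::packageVersion("polyAcode"))
}
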