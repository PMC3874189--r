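# CCCH zinc-finger detection and the adenosine stoichiometry code.
#
# A CCCH finger is matched as C-x(a..b)-C-x(c..d)-C-x(e)-H. The code reads
# two positions of each matched finger: two residues after the first Cys and
# two residues after the third Cys. An aromatic residue at both positions
# predicts a two-adenosine finger, at exactly one a single-adenosine finger,
# at neither a non-binding finger. The conserved Lys/Arg directly after the
# first Cys stacks against the base and donates the backbone amide that
# reads the purine N1/N7, so it is reported as a feature but does not change
# the count.

#' Detect CCCH zinc-finger motifs in a protein sequence
#'
#' Scans for the pattern `C-x(a..b)-C-x(c..d)-C-x(e)-H` with configurable
#' loop-length bounds. The scan is greedy left-to-right: at each candidate
#' first cysteine the motif with the shortest total loop length is taken
#' (ties broken by the earlier second, then third cysteine) and the scan
#' resumes after its histidine, which resolves overlapping candidates the
#' way tandem finger arrays are laid out.
#'
#' @param seq a [protein_sequence()] (or plain string).
#' @param spacing loop-length bounds, a list with integer pairs `loop1`,
#'   `loop2`, `loop3`; default `default_config()$spacing`, i.e.
#'   `C-x(4..8)-C-x(4..6)-C-x(3)-H`.
#' @return data frame of class `znf_motifs`, one row per finger, with
#'   author-numbered positions `c1`, `c2`, `c3`, `h`, loop lengths
#'   `loop1..loop3`, and `span_sequence` (residues c1..h inclusive).
#' @export
#' @examples
#' s <- protein_sequence("toy", "GGCAKAYACAAAACAAAHGG")
#' detect_ccch_fingers(s)
detect_ccch_fingers <- function(seq, spacing = default_config()$spacing) {
  seq <- as_protein_sequence(seq)
  check_spacing(spacing)
  res <- strsplit(seq$residues, "")[[1L]]
  n <- length(res)
  rows <- list()
  i <- 1L
  while (i <= n) {
    if (res[i] == "C") {
      cand <- ccch_candidates_at(res, i, spacing)
      if (nrow(cand)) {
        # shortest total loop = smallest h - c1; ties by c2 then c3
        cand <- cand[order(cand$h - cand$c1, cand$c2, cand$c3), , drop = FALSE]
        best <- cand[1L, ]
        rows[[length(rows) + 1L]] <- best
        i <- best$h + 1L
        next
      }
    }
    i <- i + 1L
  }
  motifs_df(rows, seq)
}

check_spacing <- function(spacing) {
  for (nm in c("loop1", "loop2", "loop3")) {
    b <- spacing[[nm]]
    if (is.null(b) || length(b) != 2L || any(b < 1L) || b[1L] > b[2L])
      stop("spacing$", nm, " must be a positive (lower, upper) pair",
           call. = FALSE)
  }
  invisible(spacing)
}

# enumerate all CCCH matches whose first cysteine is string index i
ccch_candidates_at <- function(res, i, spacing) {
  n <- length(res)
  out <- list()
  for (c2 in (i + spacing$loop1[1L] + 1L):(i + spacing$loop1[2L] + 1L)) {
    if (c2 > n || res[c2] != "C") next
    for (c3 in (c2 + spacing$loop2[1L] + 1L):(c2 + spacing$loop2[2L] + 1L)) {
      if (c3 > n || res[c3] != "C") next
      for (e in spacing$loop3[1L]:spacing$loop3[2L]) {
        h <- c3 + e + 1L
        if (h > n || res[h] != "H") next
        out[[length(out) + 1L]] <-
          data.frame(c1 = i, c2 = c2, c3 = c3, h = h)
      }
    }
  }
  if (!length(out)) return(data.frame(c1 = integer(), c2 = integer(),
                                      c3 = integer(), h = integer()))
  do.call(rbind, out)
}

motifs_df <- function(rows, seq) {
  off <- seq$numbering_offset - 1L
  if (!length(rows)) {
    df <- data.frame(parent_id = character(), c1 = integer(),
                     c2 = integer(), c3 = integer(), h = integer(),
                     loop1 = integer(), loop2 = integer(), loop3 = integer(),
                     span_sequence = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("znf_motifs", class(df))
    return(df)
  }
  m <- do.call(rbind, rows)
  df <- data.frame(
    parent_id = seq$id,
    c1 = m$c1 + off, c2 = m$c2 + off, c3 = m$c3 + off, h = m$h + off,
    loop1 = m$c2 - m$c1 - 1L,
    loop2 = m$c3 - m$c2 - 1L,
    loop3 = m$h - m$c3 - 1L,
    span_sequence = substring(seq$residues, m$c1, m$h),
    stringsAsFactors = FALSE)
  df <- df[order(df$c1), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("znf_motifs", class(df))
  df
}

#' Extract code features from detected fingers
#'
#' Reads the residues at the three code positions of each finger span:
#' directly after the first cysteine (`basic_after_c1`, Lys/Arg), two after
#' the first cysteine (`aromatic_c1p2`) and two after the third cysteine
#' (`aromatic_c3p2`). `exception_leu_his` flags the finger-1-style layout
#' (Leu after the first Cys combined with His two after the third Cys).
#' All features are pure functions of `span_sequence`; an `X` at a code
#' position counts as neither aromatic nor basic.
#'
#' @param fingers `znf_motifs` data frame from [detect_ccch_fingers()].
#' @param aromatic,basic residue code sets; defaults \{F,Y,W\} and \{K,R\}.
#' @return the input with logical columns `basic_after_c1`, `aromatic_c1p2`,
#'   `aromatic_c3p2`, `exception_leu_his` appended (class `znf_features`).
#' @export
extract_features <- function(fingers,
                             aromatic = default_config()$aromatic,
                             basic = default_config()$basic) {
  stopifnot(is.data.frame(fingers))
  span_at <- function(span, k) {
    if (k > nchar(span))
      stop("code position beyond finger span (sequence truncated?)",
           call. = FALSE)
    substring(span, k, k)
  }
  n <- nrow(fingers)
  r_c1p1 <- r_c1p2 <- r_c3p2 <- character(n)
  for (j in seq_len(n)) {
    span <- fingers$span_sequence[j]
    c3_in_span <- fingers$c3[j] - fingers$c1[j] + 1L
    r_c1p1[j] <- span_at(span, 2L)
    r_c1p2[j] <- span_at(span, 3L)
    r_c3p2[j] <- span_at(span, c3_in_span + 2L)
  }
  fingers$res_c1p1 <- r_c1p1
  fingers$res_c1p2 <- r_c1p2
  fingers$res_c3p2 <- r_c3p2
  fingers$basic_after_c1 <- r_c1p1 %in% basic
  fingers$aromatic_c1p2 <- r_c1p2 %in% aromatic
  fingers$aromatic_c3p2 <- r_c3p2 %in% aromatic
  fingers$exception_leu_his <- r_c1p1 == "L" & r_c3p2 == "H"
  class(fingers) <- unique(c("znf_features", class(fingers)))
  fingers
}

#' Predict per-finger adenosine-binding stoichiometry
#'
#' Applies the residue code: two aromatic code positions (or the Leu/His
#' exception, if enabled) predict two bound adenosines; exactly one aromatic
#' position predicts one; neither predicts none.
#'
#' @param features output of [extract_features()].
#' @param leu_his_exception logical; apply the finger-1-style exception
#'   (default `TRUE`).
#' @return the input with integer column `n_adenosines` (0, 1 or 2) and
#'   character column `rationale` (`BOTH_AROMATIC`, `ONE_AROMATIC`, `NONE`
#'   or `LEU_HIS_EXCEPTION`) appended (class `znf_calls`).
#' @export
predict_stoichiometry <- function(features,
                                  leu_his_exception =
                                    default_config()$leu_his_exception) {
  stopifnot(is.data.frame(features))
  need <- c("aromatic_c1p2", "aromatic_c3p2", "exception_leu_his")
  if (!all(need %in% names(features)))
    stop("features lack code columns; run extract_features() first",
         call. = FALSE)
  both <- features$aromatic_c1p2 & features$aromatic_c3p2
  one <- xor(features$aromatic_c1p2, features$aromatic_c3p2)
  exc <- leu_his_exception & features$exception_leu_his
  features$n_adenosines <- ifelse(both | exc, 2L, ifelse(one, 1L, 0L))
  features$rationale <- ifelse(both, "BOTH_AROMATIC",
                        ifelse(exc, "LEU_HIS_EXCEPTION",
                        ifelse(one, "ONE_AROMATIC", "NONE")))
  class(features) <- unique(c("znf_calls", class(features)))
  features
}

#' Total adenosine-binding capacity of a finger array
#'
#' @param calls `znf_calls` data frame from [predict_stoichiometry()], or an
#'   integer vector of per-finger counts.
#' @return integer sum of per-finger adenosine counts.
#' @export
#' @examples
#' predict_array_capacity(c(2L, 1L, 2L))  # 5
predict_array_capacity <- function(calls) {
  if (is.data.frame(calls)) {
    if (!"n_adenosines" %in% names(calls))
      stop("calls lack n_adenosines; run predict_stoichiometry() first",
           call. = FALSE)
    calls <- calls$n_adenosines
  }
  if (!length(calls)) stop("empty call list", call. = FALSE)
  if (any(is.na(calls)) || any(calls < 0L) || any(calls > 2L))
    stop("per-finger calls must be integers in 0..2", call. = FALSE)
  as.integer(sum(calls))
}

#' Explain why a base can or cannot be read by a CCCH finger
#'
#' The recognition chemistry requires a hydrogen-bond *donor* at the purine
#' 6-position (adenine N6 amine) to reach the sulfur of a zinc-coordinated
#' cysteine -- whose own proton is lost on Zn binding, so the sulfur can only
#' accept -- plus an N7 (or N1) acceptor for the neighbouring backbone amide.
#' Guanine presents the acceptor O6 instead of a donor and cannot H-bond to
#' the thiolate; cytosine has an N4 donor but lacks N7 so loses the second
#' bond and binds only weakly; uracil, like guanine, presents a carbonyl.
#'
#' @param base one of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return list of class `base_specificity` with fields `base`,
#'   `n6_equivalent_is_donor`, `has_n7`, `predicted_class`
#'   (`"binder"`, `"weak"` or `"non-binder"`) and `explanation`.
#' @export
explain_base_specificity <- function(base) {
  base <- toupper(as.character(base))
  if (length(base) != 1L || !base %in% c("A", "C", "G", "U"))
    stop("base must be one of A, C, G, U", call. = FALSE)
  donor <- switch(base, A = TRUE, C = TRUE, G = FALSE, U = FALSE)
  n7 <- switch(base, A = TRUE, G = TRUE, C = FALSE, U = FALSE)
  cls <- if (donor && n7) "binder" else if (donor) "weak" else "non-binder"
  expl <- switch(base,
    A = "N6_DONOR_TO_ZNCYS_SG_AND_N7_ACCEPTOR_FOR_BACKBONE_NH",
    C = "N4_DONOR_OK_BUT_NO_N7_SECOND_HBOND_LOST",
    G = "O6_ACCEPTOR_CANNOT_DONATE_TO_ZN_BOUND_THIOLATE",
    U = "O4_CARBONYL_ANALOGOUS_TO_GUANINE_NO_DONOR")
  structure(list(base = base, n6_equivalent_is_donor = donor,
                 has_n7 = n7, predicted_class = cls, explanation = expl),
            class = "base_specificity")
}

#' @export
print.base_specificity <- function(x, ...) {
  cat("<base_specificity> ", x$base, ": ", x$predicted_class,
      " (", x$explanation, ")\n", sep = "")
  invisible(x)
}

#' Detect fingers and call stoichiometry in one step
#'
#' Convenience wrapper: detect, extract features, predict per-finger counts.
#'
#' @inheritParams detect_ccch_fingers
#' @param config full config list; spacing, aromatic/basic sets and the
#'   exception flag are taken from it.
#' @return `znf_calls` data frame (possibly zero rows).
#' @export
call_finger_array <- function(seq, config = default_config()) {
  fingers <- detect_ccch_fingers(seq, spacing = config$spacing)
  if (!nrow(fingers)) return(predict_stoichiometry(
    extract_features(fingers, config$aromatic, config$basic),
    config$leu_his_exception))
  feats <- extract_features(fingers, config$aromatic, config$basic)
  predict_stoichiometry(feats, config$leu_his_exception)
}
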