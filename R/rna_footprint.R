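# Transcript scanning for candidate binding sites: A-rich windows sized to
# a finger array's footprint, literal motifs, and poly(A) runs.
#
# The footprint model: a tandem array with per-finger stoichiometries
# (k1, k2, ...) reads K = sum(k) key adenosines spread over a span of S
# nucleotides; the S - K remaining positions are spacers whose base
# identity is not read. A window of S nucleotides containing at least K
# adenosines can therefore present a key adenosine to every binding
# pocket.

#' Describe a finger array's RNA footprint
#'
#' @param stoichiometries integer vector of per-finger adenosine counts
#'   (each 0..2), e.g. `c(2, 1, 2)`.
#' @param span window span S in nucleotides. Default: 8 for a three-finger
#'   array (the paradigm case of a three-finger module covering eight
#'   nucleotides); otherwise `K + (n_fingers - 1)` as a one-spacer-per-gap
#'   heuristic.
#' @return list of class `array_footprint` with `stoichiometries`,
#'   `required_adenosines` (K) and `span` (S), K <= S.
#' @export
#' @examples
#' array_footprint(c(2, 1, 2))  # K = 5, S = 8
array_footprint <- function(stoichiometries, span = NULL) {
  stoichiometries <- as.integer(stoichiometries)
  if (!length(stoichiometries) || any(is.na(stoichiometries)) ||
      any(stoichiometries < 0L) || any(stoichiometries > 2L))
    stop("stoichiometries must be integers in 0..2", call. = FALSE)
  k <- sum(stoichiometries)
  if (is.null(span)) {
    span <- if (length(stoichiometries) == 3L) 8L
    else k + length(stoichiometries) - 1L
  }
  span <- as.integer(span)
  if (span < 1L || k > span)
    stop("span must satisfy 1 <= K <= S", call. = FALSE)
  structure(list(stoichiometries = stoichiometries,
                 required_adenosines = k, span = span),
            class = "array_footprint")
}

#' @export
print.array_footprint <- function(x, ...) {
  cat("<array_footprint> fingers (",
      paste(x$stoichiometries, collapse = ","), "): K = ",
      x$required_adenosines, " adenosines in S = ", x$span, " nt\n",
      sep = "")
  invisible(x)
}

#' Scan a transcript for A-rich windows fitting a footprint
#'
#' Reports every window of length S containing at least K adenosines, in
#' ascending start order, with 0-based half-open coordinates. Scanning is
#' single-strand (mRNA semantics); case and T/U spelling are normalised by
#' [rna_seq()].
#'
#' @param rna [rna_seq()] or base string.
#' @param fp [array_footprint()].
#' @param merge logical; merge overlapping hits into maximal intervals
#'   (default `FALSE`). Merged intervals report the maximum window score.
#' @return data frame of class `motif_hits`: `seq_id`, `start`, `end`,
#'   `n_adenosines`, `score` (adenosine count capped at K), `type`.
#'   Sequences shorter than S yield an empty frame with a warning.
#' @export
#' @examples
#' scan_windows("AAAAAAAAAAAG", array_footprint(c(2, 1, 2)))
scan_windows <- function(rna, fp, merge = FALSE) {
  rna <- as_rna_seq(rna)
  stopifnot(inherits(fp, "array_footprint"))
  s <- fp$span; k <- fp$required_adenosines
  n <- nchar(rna$bases)
  if (n < s) {
    warning("sequence ", rna$id, " shorter than the footprint span",
            call. = FALSE)
    return(empty_hits_df())
  }
  is_a <- as.integer(strsplit(rna$bases, "")[[1L]] == "A")
  cs <- c(0L, cumsum(is_a))
  starts0 <- 0:(n - s)                       # 0-based
  counts <- cs[starts0 + s + 1L] - cs[starts0 + 1L]
  keep <- counts >= k
  n_hits <- sum(keep)
  hits <- data.frame(seq_id = rep(rna$id, n_hits),
                     start = starts0[keep],
                     end = starts0[keep] + s,
                     n_adenosines = counts[keep],
                     score = pmin(counts[keep], k),
                     type = rep("a_rich_window", n_hits),
                     stringsAsFactors = FALSE)
  if (merge && nrow(hits) > 1L) hits <- merge_hits(hits)
  class(hits) <- c("motif_hits", class(hits))
  hits
}

merge_hits <- function(hits) {
  hits <- hits[order(hits$start), , drop = FALSE]
  out <- hits[1L, , drop = FALSE]
  for (i in 2L:nrow(hits)) {
    last <- nrow(out)
    if (hits$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], hits$end[i])
      out$n_adenosines[last] <- max(out$n_adenosines[last],
                                    hits$n_adenosines[i])
      out$score[last] <- max(out$score[last], hits$score[i])
    } else out <- rbind(out, hits[i, , drop = FALSE])
  }
  out$type <- "a_rich_region"
  rownames(out) <- NULL
  out
}

empty_hits_df <- function() {
  df <- data.frame(seq_id = character(), start = integer(),
                   end = integer(), n_adenosines = integer(),
                   score = integer(), type = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("motif_hits", class(df))
  df
}

#' Find exact occurrences of a literal motif
#'
#' @param rna [rna_seq()] or base string.
#' @param motif literal motif over A/C/G/U (T accepted), e.g. the
#'   co-immunoprecipitation consensus `"AAAAAAAAAAAG"`.
#' @return `motif_hits` data frame with 0-based half-open coordinates and
#'   `exact_match = TRUE`.
#' @export
find_exact_motif <- function(rna, motif) {
  rna <- as_rna_seq(rna)
  motif <- as_rna_seq(motif, id = "motif")$bases
  m <- nchar(motif)
  starts <- integer()
  from <- 1L
  repeat {
    p <- regexpr(motif, substring(rna$bases, from), fixed = TRUE)
    if (p < 0L) break
    starts <- c(starts, from + p - 1L)
    from <- from + p       # allow overlapping occurrences
    if (from + m - 1L > nchar(rna$bases)) break
  }
  n_a <- vapply(starts, function(st)
    sum(strsplit(substring(rna$bases, st, st + m - 1L), "")[[1L]] == "A"),
    integer(1))
  df <- data.frame(seq_id = rep(rna$id, length(starts)),
                   start = starts - 1L, end = starts - 1L + m,
                   n_adenosines = n_a, score = n_a,
                   type = rep("exact_motif", length(starts)),
                   stringsAsFactors = FALSE)
  df$exact_match <- rep(TRUE, nrow(df))
  class(df) <- c("motif_hits", class(df))
  df
}

#' Maximal poly(A) runs
#'
#' @param rna [rna_seq()] or base string.
#' @param min_len minimum run length (>= 1).
#' @return data frame with 0-based half-open `start`, `end` of every
#'   maximal adenosine run of at least `min_len`.
#' @export
#' @examples
#' poly_a_runs("AAAAAAAA", 8)  # one run [0, 8)
poly_a_runs <- function(rna, min_len = 8L) {
  rna <- as_rna_seq(rna)
  min_len <- as.integer(min_len)
  if (min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  r <- rle(strsplit(rna$bases, "")[[1L]] == "A")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  data.frame(seq_id = rep(rna$id, sum(keep)), start = starts[keep],
             end = ends[keep], length = r$lengths[keep],
             type = rep("poly_a_run", sum(keep)),
             stringsAsFactors = FALSE)
}
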