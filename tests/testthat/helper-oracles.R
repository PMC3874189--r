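# Independent oracles used to cross-check the package implementations.
# Each one is written from the definition, not from the package code path
# it checks.

# Brute-force CCCH scan: enumerate every (c1, c2, c3, h) tuple that
# satisfies the pattern, then apply the same published selection policy
# (greedy left-to-right, shortest total loop, ties by earlier c2/c3)
# by explicit enumeration rather than the package's incremental scan.
oracle_ccch_scan <- function(residues, spacing = default_config()$spacing) {
  res <- strsplit(residues, "")[[1L]]
  n <- length(res)
  tuples <- list()
  for (c1 in seq_len(n)) {
    if (res[c1] != "C") next
    for (c2 in seq_len(n)) {
      if (c2 <= c1 || res[c2] != "C") next
      l1 <- c2 - c1 - 1L
      if (l1 < spacing$loop1[1L] || l1 > spacing$loop1[2L]) next
      for (c3 in seq_len(n)) {
        if (c3 <= c2 || res[c3] != "C") next
        l2 <- c3 - c2 - 1L
        if (l2 < spacing$loop2[1L] || l2 > spacing$loop2[2L]) next
        for (h in seq_len(n)) {
          if (h <= c3 || res[h] != "H") next
          l3 <- h - c3 - 1L
          if (l3 < spacing$loop3[1L] || l3 > spacing$loop3[2L]) next
          tuples[[length(tuples) + 1L]] <- c(c1, c2, c3, h)
        }
      }
    }
  }
  if (!length(tuples))
    return(matrix(integer(), ncol = 4L,
                  dimnames = list(NULL, c("c1", "c2", "c3", "h"))))
  m <- do.call(rbind, tuples)
  colnames(m) <- c("c1", "c2", "c3", "h")
  # greedy selection
  picked <- list()
  cursor <- 1L
  repeat {
    avail <- m[m[, "c1"] >= cursor, , drop = FALSE]
    if (!nrow(avail)) break
    c1min <- min(avail[, "c1"])
    cand <- avail[avail[, "c1"] == c1min, , drop = FALSE]
    ord <- order(cand[, "h"] - cand[, "c1"], cand[, "c2"], cand[, "c3"])
    # if no candidate starts exactly at the next possible C we still must
    # walk c1 forward; handled by taking the smallest available c1
    best <- cand[ord[1L], ]
    picked[[length(picked) + 1L]] <- best
    cursor <- best[["h"]] + 1L
  }
  do.call(rbind, picked)
}

# Horn's quaternion method for optimal rigid superposition RMSD
oracle_quaternion_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a0 <- sweep(a, 2L, colMeans(a))
  b0 <- sweep(b, 2L, colMeans(b))
  m <- t(b0) %*% a0
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz), 4L, 4L,
    byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(a0^2) + sum(b0^2) - 2 * lam) / nrow(a)
  sqrt(max(0, e2))
}

# windowed A-count scan by direct substring counting
oracle_scan_windows <- function(bases, span, k) {
  n <- nchar(bases)
  if (n < span) return(integer())
  starts0 <- integer()
  for (i in seq_len(n - span + 1L)) {
    w <- substring(bases, i, i + span - 1L)
    n_a <- sum(strsplit(w, "")[[1L]] == "A")
    if (n_a >= k) starts0 <- c(starts0, i - 1L)
  }
  starts0
}

# maximal A-runs by character walk
oracle_poly_a_runs <- function(bases, min_len) {
  ch <- strsplit(bases, "")[[1L]]
  runs <- list(); start <- NA_integer_
  for (i in seq_along(ch)) {
    if (ch[i] == "A" && is.na(start)) start <- i
    if ((ch[i] != "A" || i == length(ch)) && !is.na(start)) {
      end <- if (ch[i] == "A") i else i - 1L
      if (end - start + 1L >= min_len)
        runs[[length(runs) + 1L]] <- c(start - 1L, end)   # 0-based, open
      start <- NA_integer_
    }
  }
  if (!length(runs)) return(matrix(integer(), ncol = 2L))
  do.call(rbind, runs)
}

# buried area of two intersecting spheres (probe-expanded radii), from
# the spherical-cap closed form
oracle_two_sphere_buried <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  stopifnot(d < R1 + R2, d > abs(R1 - R2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  2 * pi * R1 * h1 + 2 * pi * R2 * h2
}

random_rigid <- function() {
  list(rotation = random_rotation(),
       translation = stats::rnorm(3, sd = 20))
}

random_protein_string <- function(len) {
  letters20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  prob <- rep(1, 20)
  prob[letters20 == "C"] <- 4   # enrich Cys/His so motifs actually occur
  prob[letters20 == "H"] <- 3
  paste(sample(letters20, len, replace = TRUE, prob = prob),
        collapse = "")
}

expected_class_of <- function(features_row) {
  if (features_row$exception_leu_his) return("leu_his")
  if (features_row$aromatic_c1p2 && features_row$aromatic_c3p2)
    return("two_aromatic")
  if (features_row$aromatic_c1p2) return("one_aromatic_c1")
  if (features_row$aromatic_c3p2) return("one_aromatic_c3")
  "none"
}
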