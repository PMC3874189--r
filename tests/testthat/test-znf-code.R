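# Finger detection and the stoichiometry code.

test_that("detection recovers the three fingers of the synthetic Ct 3-5 region", {
  s <- nab2_ct_znf35_synthetic()
  fingers <- detect_ccch_fingers(s)
  expect_equal(nrow(fingers), 3L)
  expect_equal(fingers$c1, c(405L, 426L, 446L))
  expect_equal(fingers$c2, c(411L, 432L, 451L))
  expect_equal(fingers$c3, c(416L, 437L, 456L))
  expect_equal(fingers$h, c(420L, 441L, 460L))
  expect_equal(fingers$loop3, rep(3L, 3))
  # spans are the literal substring c1..h
  expect_true(all(substr(fingers$span_sequence, 1, 1) == "C"))
  expect_true(all(substring(fingers$span_sequence,
                            nchar(fingers$span_sequence)) == "H"))
})

test_that("sequences without the motif give an empty result", {
  no_cys <- protein_sequence("nc", "AAAAKAAARAAAFAAAYAAAHAAA")
  expect_equal(nrow(detect_ccch_fingers(no_cys)), 0L)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(protein_sequence("e", ""), "empty")
  expect_error(protein_sequence("e", "ACDB"), "B")
  expect_error(protein_sequence("e", "ACD", numbering_offset = -1),
               "numbering_offset")
  expect_error(detect_ccch_fingers(protein_sequence("x", "ACD"),
                                   spacing = list(loop1 = c(8, 4),
                                                  loop2 = c(4, 6),
                                                  loop3 = c(3, 3))),
               "loop1")
})

test_that("two planted motifs are found at their exact offsets", {
  arr <- make_finger_array(c("two_aromatic", "none"), seed = 1)
  fingers <- detect_ccch_fingers(arr)
  expect_equal(nrow(fingers), 2L)
  ora <- oracle_ccch_scan(arr$residues)
  expect_equal(fingers$c1, unname(ora[, "c1"]))
  expect_equal(fingers$h, unname(ora[, "h"]))
})

test_that("scanner equals brute-force enumeration on random sequences", {
  for (seed in 1:100) {
    withr::with_seed(seed, {
      len <- sample(50:500, 1L)
      str <- random_protein_string(len)
    })
    got <- detect_ccch_fingers(protein_sequence("r", str))
    ora <- oracle_ccch_scan(str)
    expect_equal(nrow(got), nrow(ora), info = paste("seed", seed))
    if (nrow(ora)) {
      expect_equal(got$c1, unname(ora[, "c1"]), info = paste("seed", seed))
      expect_equal(got$c2, unname(ora[, "c2"]), info = paste("seed", seed))
      expect_equal(got$c3, unname(ora[, "c3"]), info = paste("seed", seed))
      expect_equal(got$h, unname(ora[, "h"]), info = paste("seed", seed))
    }
  }
})

test_that("appending residues never changes earlier calls", {
  for (seed in 1:20) {
    withr::with_seed(seed, str <- random_protein_string(200))
    before <- call_finger_array(protein_sequence("m", str))
    withr::with_seed(seed + 1000L,
                     tail_str <- paste(sample(c("A", "G", "S", "T"), 50,
                                              replace = TRUE),
                                       collapse = ""))
    after <- call_finger_array(protein_sequence("m", paste0(str, tail_str)))
    expect_gte(nrow(after), nrow(before))
    if (nrow(before)) {
      keep <- seq_len(nrow(before))
      expect_equal(after$c1[keep], before$c1)
      expect_equal(after$n_adenosines[keep], before$n_adenosines)
    }
  }
})

test_that("code features read the right positions of the Ct fingers", {
  feats <- extract_features(detect_ccch_fingers(nab2_ct_znf35_synthetic()))
  # finger 3: Lys after Cys405, Tyr407, Phe418
  expect_true(feats$basic_after_c1[1])
  expect_true(feats$aromatic_c1p2[1])
  expect_true(feats$aromatic_c3p2[1])
  expect_equal(feats$res_c1p2[1], "Y")
  # finger 4: aromatic only after the third cysteine
  expect_true(feats$basic_after_c1[2])
  expect_false(feats$aromatic_c1p2[2])
  expect_true(feats$aromatic_c3p2[2])
  # finger 5: both aromatic
  expect_true(feats$aromatic_c1p2[3] && feats$aromatic_c3p2[3])
})

test_that("all-alanine loops carry no features", {
  s <- protein_sequence("ala", "GGCAAAAACAAAACAAAHGG")
  feats <- extract_features(detect_ccch_fingers(s))
  expect_equal(nrow(feats), 1L)
  expect_false(any(feats$basic_after_c1, feats$aromatic_c1p2,
                   feats$aromatic_c3p2, feats$exception_leu_his))
  expect_equal(predict_stoichiometry(feats)$n_adenosines, 0L)
})

test_that("stoichiometry mapping follows the code for every class", {
  cases <- list(two_aromatic = 2L, one_aromatic_c1 = 1L,
                one_aromatic_c3 = 1L, none = 0L, leu_his = 2L)
  for (cls in names(cases)) {
    for (seed in 1:5) {
      calls <- call_finger_array(make_finger_sequence(cls, seed = seed))
      expect_equal(nrow(calls), 1L, info = cls)
      expect_equal(calls$n_adenosines, cases[[cls]],
                   info = paste(cls, "seed", seed))
    }
  }
  # rationale labels
  lab <- function(cls) call_finger_array(
    make_finger_sequence(cls, seed = 1))$rationale
  expect_equal(lab("two_aromatic"), "BOTH_AROMATIC")
  expect_equal(lab("one_aromatic_c3"), "ONE_AROMATIC")
  expect_equal(lab("none"), "NONE")
  expect_equal(lab("leu_his"), "LEU_HIS_EXCEPTION")
})

test_that("the Leu/His exception is optional", {
  feats <- extract_features(detect_ccch_fingers(
    make_finger_sequence("leu_his", seed = 2)))
  on_call <- predict_stoichiometry(feats, leu_his_exception = TRUE)
  off_call <- predict_stoichiometry(feats, leu_his_exception = FALSE)
  expect_equal(on_call$n_adenosines, 2L)
  expect_equal(off_call$n_adenosines, 0L)
})

test_that("X at a code position counts as neither aromatic nor basic", {
  s <- protein_sequence("x", "GGCXXAAAACAAAACAXAHGG")
  feats <- extract_features(detect_ccch_fingers(s))
  expect_false(feats$basic_after_c1)
  expect_false(feats$aromatic_c1p2)
  expect_false(feats$aromatic_c3p2)
})

test_that("array capacity is the sum of per-finger calls, bounded 0..2", {
  expect_equal(predict_array_capacity(c(2L, 1L, 2L)), 5L)
  expect_equal(predict_array_capacity(0L), 0L)
  expect_error(predict_array_capacity(integer()), "empty")
  expect_error(predict_array_capacity(c(1L, 3L)), "0..2")
  for (seed in 1:10) {
    classes <- withr::with_seed(seed, sample(
      c("two_aromatic", "one_aromatic_c1", "one_aromatic_c3", "none"),
      4, replace = TRUE))
    calls <- call_finger_array(make_finger_array(classes, seed = seed))
    expect_true(all(calls$n_adenosines %in% 0:2))
    expect_equal(predict_array_capacity(calls), sum(calls$n_adenosines))
  }
})

test_that("detection and calls are deterministic", {
  s <- make_finger_array(c("two_aromatic", "one_aromatic_c3"), seed = 7)
  expect_identical(call_finger_array(s), call_finger_array(s))
})

test_that("base specificity verdicts follow the H-bond chemistry", {
  a <- explain_base_specificity("A")
  expect_equal(a$predicted_class, "binder")
  expect_true(a$n6_equivalent_is_donor && a$has_n7)
  c_ <- explain_base_specificity("C")
  expect_equal(c_$predicted_class, "weak")
  expect_true(c_$n6_equivalent_is_donor)
  expect_false(c_$has_n7)
  g <- explain_base_specificity("G")
  expect_equal(g$predicted_class, "non-binder")
  expect_false(g$n6_equivalent_is_donor)
  expect_equal(explain_base_specificity("U")$predicted_class, "non-binder")
  expect_error(explain_base_specificity("T"), "A, C, G, U")
})
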