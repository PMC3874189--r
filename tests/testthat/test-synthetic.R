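# The fixture generators themselves: determinism, class round trips,
# planted geometry, background composition.

test_that("generators are byte-identical for the same spec and seed", {
  expect_identical(make_finger_sequence("two_aromatic", seed = 12),
                   make_finger_sequence("two_aromatic", seed = 12))
  expect_identical(make_transcript(300, seed = 4),
                   make_transcript(300, seed = 4))
  m1 <- make_mini_complex(c(2L, 1L), seed = 6)
  m2 <- make_mini_complex(c(2L, 1L), seed = 6)
  expect_identical(m1$model$atoms, m2$model$atoms)
  expect_false(identical(make_transcript(300, seed = 4),
                         make_transcript(300, seed = 5)))
})

test_that("finger classes round-trip through feature extraction", {
  classes <- c("two_aromatic", "one_aromatic_c1", "one_aromatic_c3",
               "none", "leu_his")
  for (seed in 1:20) {
    cls <- classes[(seed %% length(classes)) + 1L]
    loops <- withr::with_seed(seed, c(sample(4:8, 1), sample(4:6, 1), 3L))
    fs <- make_finger_sequence(cls, loops = loops, seed = seed)
    feats <- extract_features(detect_ccch_fingers(fs))
    expect_equal(nrow(feats), 1L, info = paste(cls, seed))
    expect_equal(expected_class_of(feats[1, ]), cls,
                 info = paste(cls, "seed", seed, "loops",
                              paste(loops, collapse = ",")))
    expect_equal(feats$loop1, loops[1], ignore_attr = TRUE)
    expect_equal(feats$loop2, loops[2], ignore_attr = TRUE)
  }
})

test_that("contact fixtures realise their geometry to high precision", {
  st <- make_contact_fixture("stack_pair", distance = 3.41, angle = 17,
                             offset = 0.6)
  got <- detect_stacking(st)
  expect_equal(got$interplanar_angle, 17, tolerance = 1e-6)
  hb <- make_contact_fixture("hbond_pair", distance = 3.456)
  expect_equal(detect_hbonds(hb)$distance, 3.456, tolerance = 1e-9)
  # boundary scan: detection flips exactly at the stacking cutoff
  eps_grid <- c(-0.1, -0.01, 0.01, 0.1)
  for (eps in eps_grid) {
    n <- nrow(detect_stacking(make_contact_fixture(
      "stack_pair", distance = 4.5 + eps)))
    expect_equal(n, as.integer(eps < 0), info = paste("eps", eps))
  }
})

test_that("mini complexes carry exactly the planted contact inventory", {
  for (spec in list(c(2L, 1L, 2L), c(1L), c(2L, 0L))) {
    mc <- make_mini_complex(spec, seed = 21)
    fp <- build_fingerprint(mc$model, mc$fingers, compute_area = FALSE)
    expect_equal(unname(fp$bases_per_finger), unname(spec),
                 info = paste(spec, collapse = ","))
    expect_equal(nrow(fp$stacking), sum(spec))
    expect_equal(sum(fp$hbonds$category == "N6->SG_ZnCys"), sum(spec))
  }
})

test_that("a rigidly moved mini complex fingerprints identically", {
  mc <- make_mini_complex(c(2L, 1L, 2L), seed = 13)
  tr <- withr::with_seed(77, random_rigid())
  moved <- transform_model(mc$model, tr$rotation, tr$translation)
  fp0 <- build_fingerprint(mc$model, mc$fingers, compute_area = FALSE)
  fp1 <- build_fingerprint(moved, mc$fingers, compute_area = FALSE)
  expect_equal(fp1$bases_per_finger, fp0$bases_per_finger)
  expect_equal(fp1$records$edge, fp0$records$edge)
})

test_that("transcripts plant motifs verbatim and honour composition", {
  tx <- make_transcript(100, planted = list(
    list(motif = "AAAAAAAAAAAG", at = 40)), seed = 3)
  expect_equal(substring(tx$bases, 41, 52), "AAAAAAAAAAAG")
  all_u <- make_transcript(50, composition = c(A = 0, C = 0, G = 0,
                                               U = 1), seed = 1)
  expect_equal(all_u$bases, strrep("U", 50))
  # empirical A fraction within 3 sigma of binomial over 50 seeds
  p <- 0.3; n <- 400L
  for (seed in 1:50) {
    tx <- make_transcript(n, composition = c(A = p, C = 0.3, G = 0.2,
                                             U = 0.2), seed = seed)
    n_a <- sum(strsplit(tx$bases, "")[[1]] == "A")
    expect_lt(abs(n_a - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9)
  }
  expect_error(make_transcript(10, planted = list(
    list(motif = "AAAA", at = 8)), seed = 1), "does not fit")
})

test_that("the fixture writer emits a loadable standard set", {
  dir <- withr::local_tempdir()
  files <- write_fixture_set(dir, seed = 2)
  expect_true(all(file.exists(files)))
  fasta <- read_fasta(files[1], type = "protein")
  expect_equal(nrow(detect_ccch_fingers(fasta[[1]])), 3L)
  model <- read_pdb(files[4])
  expect_length(find_zn_sites(model), 3L)
})
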