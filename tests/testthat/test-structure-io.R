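# Structure model construction, PDB/FASTA round trips, config files.

test_that("structure model classifies chains and rejects bad input", {
  mc <- make_mini_complex(c(1L), seed = 3)
  m <- mc$model
  expect_s3_class(m, "structure_model")
  expect_setequal(unique(m$atoms$polymer[m$atoms$chain == "R"]), "rna")
  expect_true("het" %in% m$atoms$polymer)   # the Zn
  # alpha carbon is carbon, not calcium
  ca <- m$atoms$elem[m$atoms$elety == "CA"]
  expect_true(all(ca == "C"))
  expect_error(structure_model(data.frame(elety = "N")), "lacks column")
  dup <- data.frame(elety = c("N", "N"), resid = "ALA", chain = "A",
                    resno = 1L, x = 0:1, y = 0, z = 0)
  expect_error(structure_model(dup), "duplicate")
  bad <- data.frame(elety = "N", resid = "ALA", chain = "A", resno = 1L,
                    x = NaN, y = 0, z = 0)
  expect_error(structure_model(bad), "non-finite")
})

test_that("PDB round trip preserves atoms, residues and coordinates", {
  mc <- make_mini_complex(c(2L, 1L), seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(mc$model, path)
  back <- read_pdb(path)
  expect_equal(nrow(back$atoms), nrow(mc$model$atoms))
  a0 <- mc$model$atoms[order(mc$model$atoms$chain, mc$model$atoms$resno,
                             mc$model$atoms$elety), ]
  a1 <- back$atoms[order(back$atoms$chain, back$atoms$resno,
                         back$atoms$elety), ]
  expect_equal(a1$resid, a0$resid)
  expect_equal(a1$resno, a0$resno)
  # PDB stores 3 decimals
  expect_equal(a1$x, a0$x, tolerance = 1e-3)
  expect_equal(a1$z, a0$z, tolerance = 1e-3)
  # detectors give the same answer after the round trip
  fp0 <- build_fingerprint(mc$model, mc$fingers, compute_area = FALSE)
  fp1 <- build_fingerprint(back, mc$fingers, compute_area = FALSE)
  expect_equal(fp1$bases_per_finger, fp0$bases_per_finger)
})

test_that("a HETATM-only file yields a het chain", {
  m <- make_contact_fixture("zn_site")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  back <- read_pdb(path)
  expect_true("ZN" %in% back$atoms$resid)
  expect_equal(unique(back$atoms$polymer[back$atoms$resid == "ZN"]),
               "het")
})

test_that("FASTA round trip preserves ids and sequences", {
  seqs <- list(nab2_ct_znf35_synthetic(),
               make_finger_sequence("none", seed = 4))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path, type = "protein")
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$id, seqs[[1]]$id)
  expect_equal(back[[1]]$residues, seqs[[1]]$residues)
  expect_equal(back[[2]]$residues, seqs[[2]]$residues)
  # lines wrap at 60 columns
  body <- readLines(path)
  expect_true(all(nchar(body[!startsWith(body, ">")]) <= 60))
})

test_that("empty FASTA gives an empty list; duplicates warn but are kept", {
  path <- withr::local_tempfile(fileext = ".fasta")
  file.create(path)
  expect_equal(read_fasta(path, type = "raw"), character())
  writeLines(c(">a", "ACDE", ">a", "GGGG"), path)
  expect_warning(recs <- read_fasta(path, type = "protein"), "duplicate")
  expect_equal(length(recs), 2L)
  writeLines(c("ACDE", ">a"), path)
  expect_error(read_fasta(path), "line 1")
})

test_that("config files round-trip losslessly and reject unknown keys", {
  cfg <- default_config()
  cfg$stacking$d_max <- 4.0
  cfg$sasa$n_points <- 240L
  cfg$aromatic <- c("F", "Y")
  path <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back, cfg)
  expect_equal(config_hash(back), config_hash(cfg))
  expect_false(config_hash(back) == config_hash(default_config()))
  writeLines("nonsense.key=1", path)
  expect_error(read_config(path), "unknown config key")
})

test_that("reports carry metadata and the expected columns", {
  calls <- call_finger_array(nab2_ct_znf35_synthetic())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_finger_report(calls, tsv)
  lines <- readLines(tsv)
  expect_match(lines[1], "^# polyAcode .* config=[0-9a-f]{32}$")
  tab <- utils::read.delim(tsv, comment.char = "#")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$n_adenosines, c(2L, 1L, 2L))
  js <- withr::local_tempfile(fileext = ".json")
  write_finger_report(calls, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$array_capacity, 5L)
  expect_equal(length(parsed$fingers), 3L)
})

test_that("motif hits are written as BED-like 0-based intervals", {
  hits <- scan_windows("AAAAAAAAAAAG", array_footprint(c(2, 1, 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_bed(hits, path)
  tab <- utils::read.delim(path, comment.char = "#")
  expect_equal(tab$start, 0:4)
  expect_equal(tab$end, tab$start + 8L)
})
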