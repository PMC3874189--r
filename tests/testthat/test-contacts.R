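# Contact detectors against idealised fixtures with exact geometry.

test_that("zn sites: tetrahedral fixture gives one site with four ligands", {
  m <- make_contact_fixture("zn_site", d_s = 2.30, d_n = 2.10)
  sites <- find_zn_sites(m)
  expect_length(sites, 1L)
  expect_equal(nrow(sites[[1]]$ligands), 4L)
  expect_false(sites[[1]]$flagged)
  # ligands sorted by distance: the His nitrogen first
  expect_equal(sites[[1]]$ligands$elety[1], "NE2")
  expect_equal(sites[[1]]$ligands$distance,
               c(2.10, 2.30, 2.30, 2.30), tolerance = 1e-9)
})

test_that("zn sites: a zinc far from any ligand is kept but flagged", {
  rows <- data.frame(elety = c("ZN", "SG"), resid = c("ZN", "CYS"),
                     chain = "A", resno = c(90L, 1L),
                     x = c(0, 5), y = 0, z = 0)
  sites <- find_zn_sites(structure_model(rows))
  expect_length(sites, 1L)
  expect_true(sites[[1]]$flagged)
  expect_equal(nrow(sites[[1]]$ligands), 0L)
})

test_that("stacking: parallel rings at 3.5 A detected, perpendicular not", {
  got <- detect_stacking(make_contact_fixture("stack_pair",
                                              distance = 3.5, angle = 0))
  expect_equal(nrow(got), 1L)
  expect_equal(got$centroid_distance, 3.5, tolerance = 1e-9)
  expect_equal(got$interplanar_angle, 0, tolerance = 1e-6)
  perp <- detect_stacking(make_contact_fixture("stack_pair",
                                               distance = 3.5,
                                               angle = 90))
  expect_equal(nrow(perp), 0L)
})

test_that("stacking thresholds act as strict boundaries", {
  hit <- function(...) nrow(detect_stacking(
    make_contact_fixture("stack_pair", ...))) == 1L
  expect_true(hit(distance = 4.4, angle = 0))
  expect_false(hit(distance = 4.6, angle = 0))
  expect_true(hit(distance = 3.5, angle = 29))
  expect_false(hit(distance = 3.5, angle = 31))
  expect_true(hit(distance = 3.4, offset = 2.4))
  expect_false(hit(distance = 3.4, offset = 2.6))
})

test_that("hbonds: N6 to Zn-cysteine SG classified, beyond cutoff absent", {
  hb <- detect_hbonds(make_contact_fixture("hbond_pair", distance = 3.3))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$category, "N6->SG_ZnCys")
  expect_equal(hb$distance, 3.3, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  none <- detect_hbonds(make_contact_fixture("hbond_pair", distance = 5.0))
  expect_equal(nrow(none), 0L)
  # sulfur cutoff boundary (3.9 A)
  expect_equal(nrow(detect_hbonds(
    make_contact_fixture("hbond_pair", distance = 3.89))), 1L)
  expect_equal(nrow(detect_hbonds(
    make_contact_fixture("hbond_pair", distance = 3.91))), 0L)
})

test_that("hbonds: without the zinc the cysteine bond is not the Zn category", {
  hb <- detect_hbonds(make_contact_fixture("hbond_pair", distance = 3.3,
                                           with_zn = FALSE))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$category, "other")
})

test_that("water bridges: an equidistant water links two bases", {
  wb <- detect_water_bridges(make_contact_fixture("water_bridge",
                                                  distance = 2.9))
  expect_equal(nrow(wb), 1L)
  expect_equal(wb$a_atom, "N6")
  expect_equal(wb$b_atom, "N6")
  expect_false(wb$a_resno == wb$b_resno)
  expect_equal(wb$dist_a, 2.9, tolerance = 1e-9)
  far <- detect_water_bridges(make_contact_fixture("water_bridge",
                                                   distance = 6))
  expect_equal(nrow(far), 0L)
})

test_that("cation-pi: axial NZ passes, in-plane NZ fails on the angle", {
  cp <- detect_cation_pi(make_contact_fixture("cation_pi",
                                              distance = 4.5,
                                              axial_angle = 0))
  expect_equal(nrow(cp), 1L)
  expect_true(cp$passes)
  expect_equal(cp$axial_angle, 0, tolerance = 1e-6)
  inplane <- detect_cation_pi(make_contact_fixture("cation_pi",
                                                   distance = 6,
                                                   axial_angle = 90))
  expect_equal(nrow(inplane), 1L)
  expect_false(inplane$passes)
  expect_equal(inplane$axial_angle, 90, tolerance = 1e-6)
})

test_that("edge classification compares N1 and N7 distances to the zinc", {
  ade <- polyAcode:::adenine_template()
  base_rows <- polyAcode:::template_rows(ade, "A", "R", 1L)
  place_zn <- function(xyz) rbind(
    base_rows,
    data.frame(elety = "ZN", resid = "ZN", chain = "A", resno = 90L,
               x = xyz[1], y = xyz[2], z = xyz[3], type = "HETATM"))
  # beyond N1, along the centroid->N1 axis: Watson-Crick edge in
  m_wc <- structure_model(place_zn(ade["N1", ] * 3))
  site <- find_zn_sites(m_wc)[[1]]
  expect_equal(classify_base_edge(m_wc, "R", 1L, site), "WatsonCrick")
  # beyond N7: Hoogsteen
  m_hg <- structure_model(place_zn(ade["N7", ] * 2.5))
  expect_equal(classify_base_edge(m_hg, "R", 1L,
                                  find_zn_sites(m_hg)[[1]]), "Hoogsteen")
  # on the perpendicular bisector of N1/N7: indeterminate
  mid <- (ade["N1", ] + ade["N7", ]) / 2
  perp <- c(0, 0, 4)
  m_ind <- structure_model(place_zn(mid + perp))
  d1 <- sqrt(sum((mid + perp - ade["N1", ])^2))
  d7 <- sqrt(sum((mid + perp - ade["N7", ])^2))
  expect_lt(abs(d1 - d7), 0.5)
  expect_equal(classify_base_edge(m_ind, "R", 1L,
                                  find_zn_sites(m_ind)[[1]]),
               "indeterminate")
  # missing N7 is a domain error
  no_n7 <- base_rows[base_rows$elety != "N7", ]
  m_bad <- structure_model(rbind(no_n7, place_zn(c(8, 0, 0))[11, ]))
  expect_error(classify_base_edge(m_bad, "R", 1L, site), "N1/N7")
})

test_that("every planted category is recovered with no false positives", {
  kinds <- c("stack_pair", "hbond_pair", "zn_site", "cation_pi",
             "water_bridge")
  for (kind in kinds) {
    m <- make_contact_fixture(kind, decoys = TRUE)
    st <- detect_stacking(m)
    hb <- detect_hbonds(m)
    wb <- detect_water_bridges(m)
    cp <- detect_cation_pi(m)
    cp_pass <- if (nrow(cp)) sum(cp$passes) else 0L
    zs <- find_zn_sites(m)
    expect_equal(nrow(st), as.integer(kind == "stack_pair"), info = kind)
    expect_equal(nrow(hb), as.integer(kind == "hbond_pair"), info = kind)
    expect_equal(nrow(wb), as.integer(kind == "water_bridge"),
                 info = kind)
    expect_equal(cp_pass, as.integer(kind == "cation_pi"), info = kind)
    # the hbond fixture carries its own Zn site by construction
    expect_equal(sum(!vapply(zs, `[[`, logical(1), "flagged")),
                 as.integer(kind %in% c("zn_site", "hbond_pair")),
                 info = kind)
  }
})

test_that("detectors are invariant under global rigid motion", {
  base <- make_contact_fixture("stack_pair", distance = 3.6, angle = 10,
                               offset = 1.0)
  ref <- detect_stacking(base)
  hb_base <- make_contact_fixture("hbond_pair", distance = 3.2)
  hb_ref <- detect_hbonds(hb_base)
  for (seed in 1:50) {
    tr <- withr::with_seed(seed, random_rigid())
    st <- detect_stacking(transform_model(base, tr$rotation,
                                          tr$translation))
    expect_equal(st$centroid_distance, ref$centroid_distance,
                 tolerance = 1e-8)
    expect_equal(st$interplanar_angle, ref$interplanar_angle,
                 tolerance = 1e-6)
    expect_equal(st$lateral_offset, ref$lateral_offset, tolerance = 1e-8)
    hb <- detect_hbonds(transform_model(hb_base, tr$rotation,
                                        tr$translation))
    expect_equal(hb$distance, hb_ref$distance, tolerance = 1e-8)
    expect_equal(hb$category, hb_ref$category)
  }
})
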