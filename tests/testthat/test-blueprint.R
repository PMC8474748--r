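test_that("blueprint construction and segment decomposition are exact", {
  bp <- make_blueprint(14, 10, 14, "GB", "GB")
  expect_identical(nrow(bp), 42L)
  seg <- blueprint_segments(bp)
  expect_identical(seg$type, c("H", "L", "H", "L", "H"))
  expect_identical(seg$length, c(14L, 2L, 10L, 2L, 14L))
  expect_identical(seg$abego[seg$type == "L"], c("GB", "GB"))
  # mixed-handedness blueprints are legal (used as a negative control)
  mixed <- make_blueprint(14, 10, 14, "GB", "GBB")
  expect_identical(blueprint_segments(mixed)$abego[c(2, 4)], c("GB", "GBB"))
  expect_error(make_blueprint(4, 10, 14, "GB", "GB"), ">= 5")
  expect_error(make_blueprint(14, 10, 14, "", "GB"), "non-empty")
  expect_error(make_blueprint(14, 10, 14, "GX", "GB"), "ABEGO")
})

test_that("blueprint files round-trip and follow the Rosetta-style dialect", {
  bp <- make_blueprint(6, 7, 6, "GBB", "BAAB")
  path <- tempfile(fileext = ".bp")
  write_blueprint(bp, path)
  expect_identical(parse_blueprint(path), bp)
  # dialect: "1 V HA" -> position 1, helix, ABEGO A
  p2 <- tempfile()
  writeLines(c("1 V HA", "2 V LG", "3 V LB", "4 V HA R"), p2)
  parsed <- parse_blueprint(p2)
  expect_identical(parsed$ss, c("H", "L", "L", "H"))
  expect_identical(parsed$abego, c("A", "G", "B", "A"))
  p3 <- tempfile()
  writeLines(c("1 V HA", "2 V"), p3)
  expect_error(parse_blueprint(p3), "line 2")
  p4 <- tempfile()
  writeLines("1 V EA", p4)
  expect_error(parse_blueprint(p4), "unsupported")
})

test_that("loop sampling honours the requested ABEGO letter by construction", {
  for (letter in c("A", "B", "E", "G")) {
    rep_val <- sample_loop_dihedrals(letter, "representative")
    expect_identical(assign_abego(rep_val["phi"], rep_val["psi"]), letter)
  }
  set.seed(61)
  draws <- replicate(300, sample_loop_dihedrals("B", "sampled", sigma = 15))
  expect_true(all(assign_abego(draws["phi", ], draws["psi", ]) == "B"))
  expect_gt(stats::sd(draws["phi", ]), 5)  # noise is actually applied
  expect_error(sample_loop_dihedrals("O"), "unsupported")
  # motif-level lookup: every stored conformer classifies to its string
  tab <- loop_torsion_table()
  for (m in names(tab$motifs)) {
    for (hand in c("L", "R")) {
      lt <- loop_torsions(m, "representative", handedness = hand)
      expect_identical(paste(assign_abego(lt$phi, lt$psi), collapse = ""), m)
    }
  }
})

test_that("assembly is deterministic and reproduces blueprint torsions", {
  bp <- make_blueprint(7, 20, 7, "GB", "GB")
  a <- assemble_backbone(bp)
  b <- assemble_backbone(bp)
  expect_identical(a$CA, b$CA)
  set.seed(62)
  s1 <- assemble_backbone(bp, mode = "sampled", loop_sigma = 8)
  set.seed(62)
  s2 <- assemble_backbone(bp, mode = "sampled", loop_sigma = 8)
  expect_identical(s1$CA, s2$CA)
  # an all-helix blueprint is one ideal helix
  allh <- make_blueprint(7, 6, 7, "GB", "GB")
  allh$ss[] <- "H"
  allh$abego[] <- "A"
  helix <- assemble_backbone(allh)
  expect_equal(residues_per_turn(helix), 3.6, tolerance = 0.1 / 3.6)
  # helix-GB-helix representative build is a hairpin
  frag <- representative_hairpin("GB")
  expect_lt(compute_geometry(frag)$theta_HH, 60)
})

test_that("the Calpha clash filter behaves as specified", {
  helix <- build_backbone(ideal_helix_df(20))
  expect_true(clash_check(helix))
  fold <- rbind(helix$CA[1:10, ], helix$CA[10:1, ] + 2)
  expect_false(clash_check(fold))
  expect_true(clash_check(fold, threshold = 0))
})

test_that("the second-helix scan is deterministic and mirror-antisymmetric", {
  res <- suppressWarnings(scan_second_helix(h_range = c(9, 14)))
  res2 <- suppressWarnings(scan_second_helix(h_range = c(9, 14)))
  expect_identical(res, res2)
  mir <- suppressWarnings(scan_second_helix(h_range = c(9, 14),
                                            mirrored = TRUE))
  expect_equal(res$best_TM_CW, mir$best_TM_CCW, tolerance = 1e-12)
  expect_equal(res$best_TM_CCW, mir$best_TM_CW, tolerance = 1e-12)
  expect_equal(res$frac_CW, mir$frac_CCW)
})

test_that("folded fractions are monotone non-increasing in the threshold", {
  res55 <- suppressWarnings(scan_second_helix(h_range = 13:15,
                                              threshold = 0.55))
  res50 <- suppressWarnings(scan_second_helix(h_range = 13:15,
                                              threshold = 0.50))
  res60 <- suppressWarnings(scan_second_helix(h_range = 13:15,
                                              threshold = 0.60))
  expect_true(all(res50$frac_CCW >= res55$frac_CCW))
  expect_true(all(res55$frac_CCW >= res60$frac_CCW))
  # the best-TM landscape itself is threshold-independent
  expect_identical(res50$best_TM_CCW, res60$best_TM_CCW)
})
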