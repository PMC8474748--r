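test_that("measured superhelical radii close on the generator parameters", {
  radii <- c(`0.75` = 6.75, `0.90` = 8.1, `1.00` = 9.0, `1.10` = 9.9,
             `1.25` = 11.25)
  for (v in names(radii)) {
    dec <- make_reference_bundle(c(20, 20, 20), "CW", as.numeric(v))
    expect_equal(measure_radius(dec), unname(radii[v]), tolerance = 0.1 / 9)
  }
})

test_that("doubling the radius doubles the measurement", {
  p1 <- crick_params(superhelical_radius = 5)
  p2 <- crick_params(superhelical_radius = 10)
  d1 <- to_updown(generate_coiled_coil(p1, 20))
  d2 <- to_updown(generate_coiled_coil(p2, 20))
  expect_equal(measure_radius(d2) / measure_radius(d1), 2, tolerance = 0.01)
})

test_that("the fitted pitch of a 200-residue generation closes on 300 A", {
  ch <- generate_coiled_coil(crick_params(), 200, n_chains = 1)[[1]]
  expect_equal(measure_pitch(ch), 300, tolerance = 15 / 300)
  expect_error(measure_pitch(ch[1:60, ]), "short")
})

test_that("the straight-axis limit gives helix axes exactly parallel to z", {
  chains <- generate_coiled_coil(crick_params(), 30, straight = TRUE)
  for (ca in chains) {
    ax <- helix_axis(ca)
    expect_gt(abs(sum(ax$direction * c(0, 0, 1))), 1 - 1e-6)
  }
})

test_that("consecutive Calpha distances are 3.8 +/- 0.1 A along each helix", {
  dec <- make_reference_bundle(c(20, 20, 20), "CW", 1.0)
  for (h in split(seq_len(60), rep(1:3, each = 20))) {
    d <- sqrt(rowSums(diff(dec$ca[h, ])^2))
    expect_true(all(abs(d - 3.8) < 0.1))
  }
})

test_that("up-down re-sorting reverses the middle helix and is an involution", {
  chains <- generate_coiled_coil(crick_params(), 20)
  dec <- to_updown(chains)
  u1 <- helix_axis(dec$ca[1:20, ])$direction
  u2 <- helix_axis(dec$ca[21:40, ])$direction
  u3 <- helix_axis(dec$ca[41:60, ])$direction
  expect_lt(sum(u1 * u2), -0.9)
  expect_gt(sum(u1 * u3), 0.9)
  twice <- to_updown(to_updown(chains))
  expect_equal(twice$ca[21:40, ], chains[[2]], tolerance = 1e-12)
  # inter-helix geometry untouched: pairwise centroid distances equal
  cent0 <- t(vapply(chains, colMeans, numeric(3)))
  cent1 <- rbind(colMeans(dec$ca[1:20, ]), colMeans(dec$ca[21:40, ]),
                 colMeans(dec$ca[41:60, ]))
  expect_equal(as.numeric(dist(cent0)), as.numeric(dist(cent1)), tolerance = 1e-9)
})

test_that("mirroring is an involution that always flips the chirality label", {
  dec <- make_reference_bundle(c(14, 10, 14), "CW", 1.0)
  m <- mirror_bundle(dec)
  expect_identical(dec$chirality, "CW")
  expect_identical(m$chirality, "CCW")
  mm <- mirror_bundle(m)
  expect_lt(max(abs(mm$ca - dec$ca)), 1e-9)
  expect_identical(mm$chirality, "CW")
  expect_identical(classify_chirality(m), "CCW")
  # enantiomers cannot be superposed by a proper rotation
  expect_gt(kabsch_superpose(m$ca, dec$ca)$rmsd, 1)
})

test_that("chirality classification is invariant under rigid motion", {
  set.seed(41)
  dec <- make_reference_bundle(c(14, 12, 14), "CCW", 1.0)
  for (k in 1:100) {
    moved <- dec
    moved$ca <- apply_transform(dec$ca, rotation_matrix(), rnorm(3, 0, 30))
    expect_identical(classify_chirality(moved), "CCW")
  }
})

test_that("radius and pitch measurements are invariant under rigid motion", {
  set.seed(42)
  dec <- make_reference_bundle(c(20, 20, 20), "CW", 1.0)
  r0 <- measure_radius(dec)
  for (k in 1:5) {
    moved <- dec
    moved$ca <- apply_transform(dec$ca, rotation_matrix(), rnorm(3, 0, 30))
    expect_equal(measure_radius(moved), r0, tolerance = 1e-9)
  }
})

test_that("non-physical parameters are rejected", {
  expect_error(crick_params(superhelical_radius = -1), "positive")
  expect_error(crick_params(pitch = 0), "positive")
  expect_error(generate_coiled_coil(crick_params(), 3), ">= 5")
})
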