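test_that("a model scored against itself gives exactly 1", {
  ca <- build_backbone(ideal_helix_df(20))$CA
  res <- tm_score(ca, ca)
  expect_equal(res$score, 1, tolerance = 1e-12)
})

test_that("d0 follows the standard length scaling with a 0.5 A floor", {
  # independent arithmetic: 1.24 * (L - 15)^(1/3) - 1.8
  expect_equal(tm_d0(20), max(0.5, 1.24 * 5^(1 / 3) - 1.8), tolerance = 1e-12)
  expect_equal(tm_d0(40), 1.24 * 25^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_identical(tm_d0(15), 0.5)
  expect_identical(tm_d0(10), 0.5)
  expect_identical(tm_d0(18), 0.5)  # formula value below the floor
})

test_that("the superposition search matches an exhaustive rigid-body oracle", {
  set.seed(51)
  pairs <- list()
  # noisy copy of a helix
  h <- build_backbone(ideal_helix_df(25))$CA
  pairs[[1]] <- list(model = h + matrix(rnorm(75, 0, 1), 25, 3), ref = h)
  # hairpin model vs ideal two-helix piece of a reference bundle
  frag <- representative_hairpin("GB", helix_length = 13)
  ref <- make_reference_bundle(c(13, 13, 13), "CW", 0.75)
  pairs[[2]] <- list(model = frag$chain$CA[c(1:13, 16:28), ],
                     ref = ref$ca[1:26, ])
  # hinged helix vs straight helix (intermediate similarity)
  hinge <- ideal_helix_df(30)
  hinge$phi[15] <- hinge$phi[15] - 25
  hinge$psi[16] <- hinge$psi[16] + 25
  pairs[[3]] <- list(model = build_backbone(hinge)$CA,
                     ref = build_backbone(ideal_helix_df(30))$CA)
  # rigidly moved copy (near-identity regime)
  pairs[[4]] <- list(model = apply_transform(h, rotation_matrix(), c(5, -3, 8)),
                     ref = h)
  for (p in pairs) {
    mine <- tm_score(p$model, p$ref)$score
    oracle <- tm_oracle(p$model, p$ref)
    expect_lt(abs(mine - oracle), 0.01)
  }
})

test_that("score is invariant under rigid motion and symmetric for equal lengths", {
  set.seed(52)
  a <- build_backbone(ideal_helix_df(20))$CA
  b <- a + matrix(rnorm(60, 0, 1.5), 20, 3)
  base <- tm_score(a, b)$score
  for (k in 1:5) {
    moved <- apply_transform(a, rotation_matrix(), rnorm(3, 0, 20))
    expect_equal(tm_score(moved, b)$score, base, tolerance = 1e-9)
  }
  expect_equal(tm_score(a, b)$score, tm_score(b, a)$score, tolerance = 1e-9)
})

test_that("increasing coordinate noise never increases the expected score", {
  set.seed(53)
  ref <- build_backbone(ideal_helix_df(25))$CA
  mean_scores <- vapply(c(0.2, 1, 3), function(s) {
    mean(replicate(12, tm_score(ref + matrix(rnorm(75, 0, s), 25, 3), ref)$score))
  }, 0)
  expect_true(all(diff(mean_scores) < 0))
})

test_that("register-shifted scoring never falls below the fixed correspondence", {
  frag <- representative_hairpin("GB")
  ref <- make_reference_bundle(c(14, 10, 14), "CW", 0.75)
  model <- assemble_backbone(make_blueprint(14, 10, 14, "GB", "GB"))
  seg <- blueprint_segments(make_blueprint(14, 10, 14, "GB", "GB"))
  mh <- lapply(which(seg$type == "H"), function(k) seg$start[k]:seg$end[k])
  rh <- list(1:14, 15:24, 25:38)
  fixed <- tm_score(model$CA, ref$ca,
                    cbind(unlist(mh), unlist(rh)))$score
  shifted <- tm_score_registered(model$CA, ref$ca, mh, rh)
  expect_gte(shifted$score, fixed)
  expect_length(shifted$shifts, 3)
})

test_that("malformed correspondences and empty score sets are rejected", {
  ca <- build_backbone(ideal_helix_df(12))$CA
  expect_error(tm_score(ca, ca[1:10, ]), "equal lengths")
  expect_error(tm_score(ca, ca, cbind(1:3, 13:15)), "out of range")
  expect_error(tm_score(ca, ca, matrix(numeric(0), 0, 2)), "non-empty")
  expect_error(count_folded(numeric(0)), "zero scores")
})

test_that("folded counting uses a strict threshold", {
  expect_equal(count_folded(c(0.54, 0.55, 0.56), 0.55), 1 / 3)
  expect_equal(count_folded(rep(1, 5)), 1)
  set.seed(54)
  draws <- runif(1000)
  expect_equal(count_folded(draws, 0.5), 0.5, tolerance = 0.05 / 0.5)
  # monotone non-increasing in the threshold
  fr <- vapply(c(0.50, 0.55, 0.60), function(t) count_folded(draws, t), 0)
  expect_true(all(diff(fr) <= 0))
})
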