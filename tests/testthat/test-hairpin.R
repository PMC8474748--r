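test_that("helix-loop-helix extraction honours the length filters exactly", {
  one <- generate_toy_chain("H12-L2-H12")
  expect_length(extract_hlh_fragments(one$chain, one$ss), 1)
  expect_length(extract_hlh_fragments(one$chain, one$ss)[[1]]$loop_range, 2)

  short <- generate_toy_chain("H9-L2-H12")
  expect_length(extract_hlh_fragments(short$chain, short$ss), 0)

  long_loop <- generate_toy_chain("H12-L11-H12")
  expect_length(extract_hlh_fragments(long_loop$chain, long_loop$ss), 0)

  two <- generate_toy_chain("H12-L2-H12-L3-H12")
  frags <- extract_hlh_fragments(two$chain, two$ss)
  expect_length(frags, 2)
  # consecutive fragments share the middle helix
  expect_identical(frags[[1]]$c_range, frags[[2]]$n_range + 14L)

  no_helix <- generate_toy_chain("L5-L5")
  expect_length(extract_hlh_fragments(no_helix$chain, no_helix$ss), 0)
})

test_that("terminal-A pruning keeps only loops starting/ending in B, E, G", {
  expect_setequal(
    vapply(prune_terminal_a(lapply(c("GB", "AB", "GA", "G", "BAAB", "EAB"),
                                   loop_stub)), `[[`, "", "loop_abego"),
    c("GB", "G", "BAAB", "EAB"))
  set.seed(31)
  pool <- c(replicate(30, paste0(sample(c("A"), 1), "B")),
            replicate(70, paste0(sample(c("B", "E", "G"), 1), "B")))
  kept <- prune_terminal_a(lapply(pool, loop_stub))
  expect_length(kept, 70)
})

test_that("an exactly antiparallel pair has near-zero crossing angle", {
  # two ideal helices joined by a half-turn loop engineered so that the
  # axes are close to antiparallel: use the shipped GB representative
  frag <- representative_hairpin("GB")
  g <- compute_geometry(frag)
  expect_lt(g$theta_HH, 60)
  expect_identical(g$handedness, "L")
})

test_that("mirroring negates phi_HH and flips the handedness label", {
  set.seed(32)
  for (motif in c("GB", "GBB", "BAAB")) {
    frag <- representative_hairpin(motif)
    g <- compute_geometry(frag)
    gm <- compute_geometry(mirror_fragment(frag))
    expect_lt(abs(gm$phi_HH + g$phi_HH), 1e-6)
    expect_identical(sort(c(g$handedness, gm$handedness)), c("L", "R"))
    expect_equal(gm$theta_HH, g$theta_HH, tolerance = 1e-9)
  }
})

test_that("theta_HH is invariant under rigid motion of the fragment", {
  set.seed(33)
  frag <- representative_hairpin("GBB")
  g0 <- compute_geometry(frag)
  for (k in 1:5) {
    R <- rotation_matrix()
    tr <- rnorm(3, 0, 20)
    moved <- frag
    for (nm in c("N", "CA", "C", "O")) {
      moved$chain[[nm]] <- apply_transform(frag$chain[[nm]], R, tr)
    }
    g <- compute_geometry(moved)
    expect_lt(abs(g$theta_HH - g0$theta_HH), 1e-9)
    expect_lt(abs(g$phi_HH - g0$phi_HH), 1e-6)
  }
})

test_that("the hairpin filter is strict at the 60 degree boundary", {
  geom <- data.frame(id = letters[1:6], source = "x", loop_abego = "GB",
                     loop_length = 2,
                     theta_HH = c(10, 30, 59.9, 60, 90, 170),
                     phi_HH = -20, handedness = "L")
  frags <- lapply(geom$id, loop_stub)
  expect_length(filter_hairpins(frags, theta_max = 60, geometry = geom), 3)
  expect_length(filter_hairpins(list(), 60), 0)
})

test_that("motif tabulation counts, ranks and normalizes per length class", {
  mk <- function(ab, n, hand, phi) {
    data.frame(id = sprintf("%s_%d_%s", ab, seq_len(n), hand), source = "x",
               loop_abego = ab, loop_length = nchar(ab), theta_HH = 20,
               phi_HH = phi, handedness = hand)
  }
  geom <- rbind(mk("GB", 50, "L", -40), mk("BB", 30, "L", -30),
                mk("GBB", 20, "R", 35))
  tab <- tabulate_motifs(geom)
  expect_identical(tab$loop_abego, c("GB", "BB", "GBB"))
  expect_identical(tab$count, c(50L, 30L, 20L))
  expect_equal(tab$frequency[1:2], c(0.625, 0.375))
  expect_equal(tab$frequency[3], 1)
  one <- tabulate_motifs(mk("GB", 10, "L", -40))
  expect_identical(one$count, 10L)
  expect_equal(one$frequency, 1)
})

test_that("motif selection applies the strict ratio rule per length class", {
  base <- data.frame(loop_length = c(2, 2, 3, 3, 4),
                     loop_abego = c("GB", "BB", "BAB", "GBB", "BAAB"),
                     count = c(100, 60, 100, 80, 60),
                     count_L = c(90, 30, 55, 9, 53),
                     count_R = c(10, 30, 45, 71, 7),
                     median_phi_HH = 0, frequency = NA, representative = "x")
  base$handedness_ratio <- pmax(base$count_L / base$count_R,
                                base$count_R / base$count_L)
  sel <- select_motifs(base, min_ratio = 5)
  expect_setequal(sel$loop_abego, c("GB", "GBB", "BAAB"))
  # ratio exactly 5 is not enough; strictly greater is required
  border <- base[1, ]
  border$handedness_ratio <- 5
  expect_identical(nrow(select_motifs(border, 5)), 0L)
  # a pure-handedness motif (infinite ratio) qualifies
  pure <- base[1, ]
  pure$count_R <- 0
  pure$handedness_ratio <- Inf
  expect_identical(select_motifs(pure, 5)$loop_abego, "GB")
})

test_that("the representative is the fragment nearest the median phi_HH", {
  mk_geom <- function(ids, phis) {
    data.frame(id = ids, source = "x", loop_abego = "GB", loop_length = 2,
               theta_HH = 20, phi_HH = phis, handedness = "L")
  }
  g <- mk_geom(c("a", "b", "c"), c(-100, -90, -80))
  frags <- lapply(g$id, loop_stub)
  expect_identical(select_representative(frags, "GB", geometry = g)$id, "b")
  g2 <- mk_geom(c("a", "b"), c(-100, -80))
  expect_identical(select_representative(lapply(g2$id, loop_stub), "GB",
                                         geometry = g2)$id, "a")
  expect_error(select_representative(frags, "ZZ", geometry = g), "no fragments")
  # median recovery on a larger draw
  set.seed(34)
  phis <- rnorm(501, -90, 15)
  g3 <- mk_geom(sprintf("f%03d", 1:501), phis)
  rep_id <- select_representative(lapply(g3$id, loop_stub), "GB",
                                  geometry = g3)$id
  expect_equal(g3$phi_HH[g3$id == rep_id], stats::median(phis))
})

test_that("the analysis pipeline order reproduces hand-computed counts", {
  # 100 synthetic loops: 30 with terminal A never reach tabulation
  set.seed(35)
  spec <- synthetic_spec(data.frame(motif = c("GB", "BAB"),
                                    handedness = c("L", "L"),
                                    count = c(40, 20), ratio = c(Inf, Inf),
                                    sigma = 3), seed = 9)
  ds <- generate_fragment_dataset(spec)
  expect_length(ds$fragments, 60)
  pruned <- prune_terminal_a(ds$fragments)
  expect_length(pruned, 60)  # shipped motifs never start/end with A
  geom <- fragment_geometry_table(pruned)
  tab <- tabulate_motifs(geom[geom$theta_HH < 60, ])
  expect_identical(tab$count[tab$loop_abego == "GB"], 40L)
  expect_identical(tab$count[tab$loop_abego == "BAB"], 20L)
})
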