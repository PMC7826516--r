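params <- default_ffparams()

test_that("adhesion energy vanishes for non-interacting groups and matches closed form", {
  # three single-atom groups mutually beyond the cutoff
  far <- triad_composite(50)
  expect_equal(adhesion_energy(far, params), 0, tolerance = 1e-10)
  # all three pairwise at the LJ minimum: three cross-pair interactions, -3 eps
  eps <- params$vdw[["CA"]][1]; sig <- params$vdw[["CA"]][2]
  near <- triad_composite(2^(1 / 6) * sig)
  expect_equal(adhesion_energy(near, params), -3 * eps, tolerance = 1e-10)
})

test_that("adhesion energy equals the direct sum of cross-group interaction terms", {
  # random small composite: three groups of LJ atoms, no cross bonds
  set.seed(21)
  mk <- function(g, dy) structure_new(rep("C", 4),
    sweep(matrix(runif(12, 0, 6), ncol = 3), 2, c(0, dy, 0), "+"),
    groups = rep(g, 4))
  s <- combine_structures(mk("upper_graphene", 5), mk("lipid_1", 0),
                          mk("lower_graphene", -5))
  # oracle: sum of LJ terms over cross-group pairs only
  eps <- params$vdw[["CA"]][1]; sig <- params$vdw[["CA"]][2]
  e_cross <- 0
  for (i in 1:11) for (j in (i + 1):12) {
    if (s$groups[i] == s$groups[j]) next
    r2 <- sum((s$positions[i, ] - s$positions[j, ])^2)
    if (r2 >= params$cutoff^2) next
    s6 <- (sig^2 / r2)^3
    e_cross <- e_cross + 4 * eps * (s6^2 - s6)
  }
  expect_equal(adhesion_energy(s, params), e_cross, tolerance = 1e-10)
  # incomplete grouping is rejected
  bad <- s; bad$groups[2] <- "stray"
  expect_error(adhesion_energy(bad, params), "partition")
})

make_mini_scene <- function() {
  # deliberately small: 8 x 8.6 flakes, one lipid-tagged LJ cluster between
  up <- build_graphene_flake(8, 8.6, group = "upper_graphene")
  lo <- build_graphene_flake(8, 8.6, group = "lower_graphene")
  up <- translate_structure(up, c(0, 3.4, 0))
  lo <- translate_structure(lo, c(0, -3.4, 0))
  set.seed(5)
  lip <- structure_new(rep("C", 6), matrix(runif(18, -2, 2), ncol = 3),
                       groups = rep("lipid_1", 6))
  comp <- combine_structures(up, lo, lip)
  tip <- build_capped_cnt(tip_spec(n = 5, target_length = 6))
  place_tip(comp, tip, gap = 4.1)
}

test_that("the protocol records exact step bookkeeping and the study's point-A coordinate", {
  sc <- make_mini_scene()
  traj <- suppressWarnings(
    run_indentation(sc, protocol_config(max_tip_coord = -2.6,
                                        retract_to = -4.1,
                                        record_stress = TRUE),
                    params, minimizer_config(max_iterations = 60)))
  rec <- traj$records
  # three 0.5 steps from -4.1: the first key coordinate of the study
  expect_equal(rec$tip_edge_coord[rec$stroke == "forward"],
               c(-4.1, -3.6, -3.1, -2.6))
  expect_true(all(abs(diff(rec$tip_edge_coord[rec$stroke == "forward"]) - 0.5) < 1e-12))
  expect_true(all(abs(diff(rec$tip_edge_coord[rec$stroke == "reverse"]) + 0.5) < 1e-12))
  # tip rigidity: pairwise distances identical across all frames
  tipidx <- which(sc$structure$groups == "tip")
  d0 <- dist(traj$frames[[1]]$positions[tipidx, ])
  for (fr in traj$frames)
    expect_equal(max(abs(dist(fr$positions[tipidx, ]) - d0)), 0, tolerance = 1e-12)
  # MLS columns present and non-negative
  expect_true(all(rec$mls_upper >= 0) && all(rec$mls_lower >= 0))
})

test_that("a protocol with zero stroke yields a single record and no displacement", {
  sc <- make_mini_scene()
  traj <- suppressWarnings(
    run_indentation(sc, protocol_config(max_tip_coord = -4.1,
                                        retract_to = -4.1,
                                        record_stress = FALSE),
                    params, minimizer_config(max_iterations = 40)))
  expect_equal(nrow(traj$records), 1L)
  expect_equal(traj$records$tip_edge_coord, -4.1)
})

test_that("far from the composite the total energy is constant across steps", {
  up <- build_graphene_flake(8, 8.6, group = "upper_graphene")
  lo <- translate_structure(build_graphene_flake(8, 8.6, group = "lower_graphene"),
                            c(0, -6.8, 0))
  comp <- combine_structures(translate_structure(up, c(0, 120, 0)),
                             translate_structure(lo, c(0, 120, 0)))
  tip <- build_capped_cnt(tip_spec(n = 5, target_length = 6))
  # tip 100+ Angstrom below the (displaced) composite: no interaction
  sc <- place_tip(comp, tip, gap = 101)
  traj <- suppressWarnings(
    run_indentation(sc, protocol_config(max_tip_coord = -99,
                                        retract_to = -101,
                                        record_stress = FALSE),
                    params, minimizer_config(max_iterations = 100),
                    mconfig_initial = minimizer_config(max_iterations = 4000)))
  expect_lt(diff(range(traj$records$e_total)), 1e-8)
})

test_that("key-point detection flags extrema, plateaus and adhesion maxima", {
  base <- data.frame(stroke = "forward", e_total = c(3, 1, 2),
                     e_adh = c(-1, -2, -1.5), step = 0:2)
  kp <- detect_key_points(base)
  expect_true(any(kp$step == 1 & kp$reason == "energy local minimum"))
  mono <- data.frame(stroke = "forward", e_total = c(1, 2, 3, 4),
                     e_adh = -c(1, 1, 1, 1), step = 0:3)
  kp2 <- detect_key_points(mono)
  expect_false(any(grepl("energy local", kp2$reason)))
  plateau <- data.frame(stroke = "forward", e_total = c(1, 2, 2, 1),
                        e_adh = -c(1, 1, 1, 1), step = 0:3)
  kp3 <- detect_key_points(plateau)
  expect_true(any(kp3$step == 1 & kp3$reason == "energy local maximum"))
  expect_error(detect_key_points(base[1:2, ]), "too short")
  # labels are assigned in order
  expect_equal(kp3$label, LETTERS[seq_len(nrow(kp3))])
})

test_that("plateau tie-break matches brute-force over all length-4 patterns", {
  # oracle: compress runs, flag interior runs strictly above/below neighbours
  oracle <- function(v) {
    r <- rle(v); st <- cumsum(r$lengths) - r$lengths + 1L
    mx <- integer(0)
    if (length(r$values) >= 3)
      for (m in 2:(length(r$values) - 1))
        if (r$values[m] > r$values[m - 1] && r$values[m] > r$values[m + 1])
          mx <- c(mx, st[m])
    mx
  }
  pats <- expand.grid(a = 1:3, b = 1:3, c = 1:3, d = 1:3)
  for (row in seq_len(nrow(pats))) {
    v <- as.numeric(pats[row, ])
    rec <- data.frame(stroke = "forward", e_total = v, e_adh = -v, step = 0:3)
    kp <- detect_key_points(rec)
    got <- sort(kp$step[kp$reason == "energy local maximum"])
    expect_equal(got, sort(oracle(v) - 1L), info = paste(v, collapse = ","))
  }
})
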