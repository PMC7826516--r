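test_that("graphene flake matches the site-enumeration oracle and errors below one cell", {
  expect_equal(n_atoms(build_graphene_flake(2.46, 4.26)), 4L)
  expect_equal(n_atoms(build_graphene_flake(2.46, 4.26)),
               oracle_honeycomb_count(2.46, 4.26))
  f <- build_graphene_flake(25.5, 35.51)
  expect_equal(n_atoms(f), oracle_honeycomb_count(25.5, 35.51))
  expect_true(all(f$elements == "C"))
  # centroid at origin
  expect_equal(colMeans(f$positions), c(0, 0, 0), tolerance = 1e-10)
  # planar, normal along the indentation axis
  expect_equal(diff(range(f$positions[, 2])), 0)
  expect_error(build_graphene_flake(0.5, 4.26), "below one honeycomb unit")
})

test_that("flake bond degrees never exceed three and interior atoms have exactly three", {
  f <- build_graphene_flake(25.5, 35.51)
  deg <- tabulate(c(f$bonds), n_atoms(f))
  expect_true(all(deg <= 3L))
  # interior = farther than one bond length from the bounding box
  pos <- f$positions
  rng_x <- range(pos[, 1]); rng_z <- range(pos[, 3])
  interior <- pos[, 1] > rng_x[1] + 1.5 & pos[, 1] < rng_x[2] - 1.5 &
              pos[, 3] > rng_z[1] + 1.5 & pos[, 3] < rng_z[2] - 1.5
  expect_true(all(deg[interior] == 3L))
  # bond lengths all at the nominal first-neighbour distance
  bl <- sqrt(rowSums((pos[f$bonds[, 1], ] - pos[f$bonds[, 2], ])^2))
  expect_equal(bl, rep(1.42, length(bl)), tolerance = 1e-6)
})

test_that("zigzag nanotube has the analytic radius and 4n atoms per open cell", {
  tube <- build_capped_cnt(tip_spec(n = 4, target_length = 4.26, cap = FALSE))
  expect_equal(n_atoms(tube), 16L)   # 4n per translational cell
  t16 <- build_capped_cnt(tip_spec(n = 16, target_length = 20))
  cyl <- t16$positions[t16$positions[, 2] > 1, ]
  r_meas <- mean(sqrt(cyl[, 1]^2 + cyl[, 3]^2))
  expect_equal(r_meas, 16 * 2.46 / (2 * pi), tolerance = 5e-3)
  expect_error(tip_spec(n = 2), "must be >= 3")
})

test_that("capped tube closes exactly one end and meets the target length", {
  t16 <- build_capped_cnt(tip_spec(n = 16, target_length = 20, cap = TRUE))
  r <- 16 * sqrt(3) * 1.42 / (2 * pi)
  rad <- sqrt(t16$positions[, 1]^2 + t16$positions[, 3]^2)
  y <- t16$positions[, 2]
  # atoms inside the cylinder wall only at the capped (min-y) end
  inside <- rad < r - 0.5
  expect_true(all(y[inside] < 0))
  expect_gt(sum(inside), 10)
  expect_equal(diff(range(y)), 20, tolerance = 1.5)
  expect_true(all(t16$groups == "tip"))
  expect_true(all(t16$frozen))
})

test_that("DPPC has the exact elemental composition and a connected bond graph", {
  d <- build_dppc(seed = 3)
  expect_equal(element_counts(d)[c("C", "H", "N", "O", "P")],
               c(C = 40L, H = 80L, N = 1L, O = 8L, P = 1L))
  expect_equal(n_atoms(d), 130L)
  expect_equal(n_atoms(combine_structures(build_dppc(1), build_dppc(2))), 260L)
  # connectivity by breadth-first search
  nb <- lapply(seq_len(130), function(i)
    c(d$bonds[d$bonds[, 1] == i, 2], d$bonds[d$bonds[, 2] == i, 1]))
  seen <- rep(FALSE, 130); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in nb[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  expect_true(all(seen))
  # determinism
  expect_identical(build_dppc(7), build_dppc(7))
  expect_false(identical(build_dppc(7)$positions, build_dppc(8)$positions))
})

test_that("supercell reproduces the study composition and placement distances", {
  s <- assemble_supercell()
  expect_equal(n_atoms(s), 878L)
  expect_equal(sum(s$groups %in% c("upper_graphene", "lower_graphene")), 618L)
  up_y <- mean(s$positions[s$groups == "upper_graphene", 2])
  lo_y <- mean(s$positions[s$groups == "lower_graphene", 2])
  expect_equal(up_y - lo_y, 2 * 6.23, tolerance = 1e-9)
  for (g in c("lipid_1", "lipid_2")) {
    ctr <- mean(s$positions[s$groups == g, 2])
    expect_equal(abs(up_y - ctr), 6.23, tolerance = 1e-6)
    expect_equal(abs(ctr - lo_y), 6.23, tolerance = 1e-6)
  }
  # empty case: two flakes only
  s0 <- assemble_supercell(composite_spec(n_lipids = 0))
  expect_equal(sort(unique(s0$groups)), c("lower_graphene", "upper_graphene"))
  # lipid too large for the gap
  expect_error(assemble_supercell(composite_spec(lipid_distance = 3)),
               "too large for the interlayer gap")
})

test_that("tiling obeys the count law, conserves elements and never overlaps atoms", {
  s <- assemble_supercell()
  frag <- tile_fragment(s, 3, 3)
  expect_equal(n_atoms(frag), 7902L)
  expect_identical(tile_fragment(s, 1, 1), s)
  small <- build_graphene_flake(5, 5)
  for (nx in 1:3) for (ny in 1:2) {
    tl <- tile_fragment(small, nx, ny)
    expect_equal(n_atoms(tl), nx * ny * n_atoms(small))
  }
  two <- tile_fragment(small, 2, 1)
  dmin <- min(dist(two$positions))
  expect_gt(dmin, 0.5)
  # element conservation under assembly and tiling
  expect_equal(sum(element_counts(frag)), 9L * sum(element_counts(s)))
  expect_equal(element_counts(frag)[["P"]], 18L)
  # lipid groups re-indexed per copy
  expect_equal(sum(grepl("^lipid_", unique(frag$groups))), 18L)
})

test_that("tip placement sets the gap and the tip-edge coordinate convention", {
  comp <- assemble_supercell()
  tip <- build_capped_cnt(tip_spec(16, 12))
  sc <- place_tip(comp, tip, gap = 4.1)
  expect_s3_class(sc, "Scene")
  expect_equal(sc$tip_edge_coord, -4.1)
  plane <- mean(sc$structure$positions[sc$structure$groups == "upper_graphene", 2])
  lead <- min(sc$structure$positions[sc$structure$groups == "tip", 2])
  expect_equal(lead - plane, 4.1, tolerance = 1e-9)
  # laterally centered
  ctr_comp <- colMeans(comp$positions)
  tip_xz <- colMeans(sc$structure$positions[sc$structure$groups == "tip", c(1, 3)])
  expect_equal(unname(tip_xz), ctr_comp[c(1, 3)], tolerance = 1e-6)
  expect_error(place_tip(comp, tip, gap = 0), "must be positive")
})

test_that("builders are deterministic and structure invariants hold", {
  expect_identical(assemble_supercell(seed = 2), assemble_supercell(seed = 2))
  expect_identical(build_capped_cnt(tip_spec(8, 10)),
                   build_capped_cnt(tip_spec(8, 10)))
  s <- assemble_supercell()
  expect_true(all(is.finite(s$positions)))
  expect_true(all(s$bonds[, 1] != s$bonds[, 2]))
  expect_true(all(s$elements %in% c("C", "H", "N", "O", "P")))
  expect_error(structure_new("X", matrix(0, 1, 3)), "element symbols")
  expect_error(structure_new("C", matrix(Inf, 1, 3)), "finite")
  expect_error(structure_new(c("C", "C"), matrix(0, 2, 3), bonds = cbind(1, 1)),
               "irreflexive")
})
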