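test_that("aufbau filling occupies the lowest orbitals and splits degenerate frontiers", {
  m <- electronic_model(diag(c(-1, 1)), diag(2), c(1, 2), c(1, 1))
  st <- solve_electronic(m)
  expect_equal(st$occupations, c(2, 0))
  expect_equal(sum(st$occupations), m$n_electrons)
  # three degenerate-ish levels, three electrons: equal frontier split
  m3 <- electronic_model(diag(c(0, 0, 1)), diag(3), 1:3, c(1, 1, 1),
                         n_electrons = 3)
  expect_equal(solve_electronic(m3)$occupations, c(1.5, 1.5, 0))
})

test_that("a symmetric dimer yields symmetric/antisymmetric orbitals and zero charges", {
  H <- matrix(c(-1, -0.3, -0.3, -1), 2)
  S <- matrix(c(1, 0.2, 0.2, 1), 2)
  m <- electronic_model(H, S, c(1, 2), c(1, 1))
  st <- solve_electronic(m)
  C <- st$coefficients
  expect_equal(abs(C[1, 1]), abs(C[2, 1]), tolerance = 1e-10)
  expect_equal(abs(C[1, 2]), abs(C[2, 2]), tolerance = 1e-10)
  expect_equal(max(abs(t(C) %*% S %*% C - diag(2))), 0, tolerance = 1e-8)
  cr <- mulliken_charges(st, m)
  expect_equal(cr$charge, c(0, 0), tolerance = 1e-10)
})

test_that("eigenvalues agree with an independent dense generalized solver", {
  set.seed(31)
  M <- 6
  A <- matrix(rnorm(M * M), M); H <- (A + t(A)) / 2
  B <- matrix(rnorm(M * M), M); S <- crossprod(B) / M + diag(M)
  m <- electronic_model(H, S, rep(1:3, each = 2), c(2, 2, 2))
  st <- solve_electronic(m)
  # oracle: unsymmetric route through solve(S) %*% H
  ev_oracle <- sort(Re(eigen(solve(S) %*% H)$values))
  expect_equal(sort(st$energies), ev_oracle, tolerance = 1e-10)
  # generalized eigen equation holds column by column
  for (k in 1:M)
    expect_equal(H %*% st$coefficients[, k],
                 st$energies[k] * S %*% st$coefficients[, k], tolerance = 1e-8)
})

test_that("gross populations obey the trace identity and hand-solved 2x2 charges", {
  H <- matrix(c(-2, -0.5, -0.5, -1), 2)
  S <- matrix(c(1, 0.4, 0.4, 1), 2)
  m <- electronic_model(H, S, c(1, 2), c(1, 1))
  st <- solve_electronic(m)
  cr <- mulliken_charges(st, m)
  expect_equal(sum(cr$gap), m$n_electrons, tolerance = 1e-10)
  # brute-force oracle: solve the 2x2 generalized problem directly
  ev <- eigen(solve(S) %*% H)
  k <- which.min(Re(ev$values))
  c1 <- Re(ev$vectors[, k])
  c1 <- c1 / sqrt(drop(t(c1) %*% S %*% c1))
  P <- 2 * tcrossprod(c1)
  gap_oracle <- diag(P %*% S)
  expect_equal(cr$gap, gap_oracle, tolerance = 1e-10)
  expect_equal(cr$charge, c(1, 1) - gap_oracle, tolerance = 1e-10)
})

test_that("charge conservation and the identity-overlap reduction hold on random models", {
  set.seed(32)
  for (rep in 1:5) {
    M <- sample(4:9, 1)
    A <- matrix(rnorm(M * M), M); H <- (A + t(A)) / 2
    B <- matrix(rnorm(M * M), M); S <- crossprod(B) / M + diag(M)
    atom_of <- sort(sample(1:3, M, replace = TRUE))
    z <- as.numeric(tabulate(atom_of, 3))          # one electron per orbital
    m <- electronic_model(H, S, atom_of, z)
    cr <- mulliken_charges(solve_electronic(m), m)
    expect_equal(sum(cr$charge), 0, tolerance = 1e-8)
    # with S = identity the gross population reduces to net Mulliken population
    mi <- electronic_model(H, diag(M), atom_of, z)
    sti <- solve_electronic(mi)
    P <- sti$coefficients %*% (sti$occupations * t(sti$coefficients))
    cri <- mulliken_charges(sti, mi)
    net <- vapply(1:3, function(a) sum(diag(P)[atom_of == a]), numeric(1))
    expect_equal(cri$gap, net, tolerance = 1e-10)
  }
})

test_that("permuting equivalent atoms permutes the charges", {
  # 4-site ring with two element types alternating: swap-equivalent sites
  H <- matrix(0, 4, 4)
  diag(H) <- c(-2, -1, -2, -1)
  for (k in 1:4) { j <- k %% 4 + 1; H[k, j] <- H[j, k] <- -0.4 }
  m <- electronic_model(H, diag(4), 1:4, c(1, 1, 1, 1))
  cr <- mulliken_charges(solve_electronic(m), m)
  expect_equal(cr$charge[1], cr$charge[3], tolerance = 1e-10)
  expect_equal(cr$charge[2], cr$charge[4], tolerance = 1e-10)
})

test_that("the toy tight-binding backend reproduces Hueckel ring spectra and block structure", {
  ring <- structure_new(rep("C", 6),
                        cbind(1.42 * cos(2 * pi * (0:5) / 6), 0,
                              1.42 * sin(2 * pi * (0:5) / 6)))
  rules <- nanoindent:::tb_defaults()
  rules$s0 <- 0; rules$cutoff <- 2.0    # first neighbours only, S = identity
  m <- build_toy_tightbinding(ring, rules)
  st <- solve_electronic(m)
  lev <- sort(st$energies - rules$onsite[["C"]]) / abs(rules$t0)
  expect_equal(lev, c(-2, -1, -1, 1, 1, 2), tolerance = 1e-8)
  # dimer: 2x2 symmetric model
  dimer <- structure_new(c("C", "C"), rbind(c(0, 0, 0), c(1.42, 0, 0)))
  md <- build_toy_tightbinding(dimer)
  expect_equal(dim(md$H), c(2L, 2L))
  expect_equal(md$H[1, 2], md$H[2, 1])
  # atoms beyond the cutoff give block-diagonal H and S
  farpair <- structure_new(c("C", "C"), rbind(c(0, 0, 0), c(10, 0, 0)))
  mf <- build_toy_tightbinding(farpair)
  expect_equal(mf$H[1, 2], 0)
  expect_equal(mf$S, diag(2))
  # hydrogens are not part of the basis
  ch <- structure_new(c("C", "H"), rbind(c(0, 0, 0), c(1.09, 0, 0)),
                      bonds = cbind(1, 2))
  expect_equal(nrow(build_toy_tightbinding(ch)$H), 1L)
  expect_error(build_toy_tightbinding(ring, max_orbitals = 3L), "too large")
})

test_that("group aggregation reproduces per-atom re-summation and the bookkeeping order", {
  set.seed(33)
  cr <- data.frame(atom = 1:10, gap = runif(10), z = 1, charge = rnorm(10))
  class(cr) <- c("ChargeReport", "data.frame")
  grouping <- c(rep("tip", 2), rep("upper_graphene", 2), rep("lipid_1", 2),
                rep("lipid_2", 2), rep("lower_graphene", 2))
  gc <- group_charges(cr, grouping)
  expect_equal(names(gc), c("tip", "upper_graphene", "lipid", "lower_graphene"))
  expect_equal(gc[["lipid"]], sum(cr$charge[5:8]), tolerance = 1e-12)
  expect_equal(gc[["tip"]], sum(cr$charge[1:2]), tolerance = 1e-12)
  expect_equal(sum(gc), sum(cr$charge), tolerance = 1e-12)
  expect_error(group_charges(cr, grouping[1:5]), "does not cover")
  # neutral scene: group charges sum to zero
  s <- assemble_supercell(composite_spec(flake_lx = 10, flake_ly = 10,
                                         sheet_atoms = NULL, n_lipids = 1))
  res <- scene_charges(s)
  expect_equal(sum(res$groups), 0, tolerance = 1e-8)
  expect_equal(sum(res$report$charge), 0, tolerance = 1e-8)
})

test_that("electronic models round-trip through plain-text matrix files", {
  set.seed(34)
  M <- 5
  A <- matrix(rnorm(M * M), M); H <- (A + t(A)) / 2
  B <- matrix(rnorm(M * M), M); S <- crossprod(B) / M + diag(M)
  dir <- tempfile(); dir.create(dir)
  wm <- function(mat, path) {
    writeLines(c(as.character(nrow(mat)),
                 apply(mat, 1, paste, collapse = " ")), path)
  }
  wm(H, file.path(dir, "h.txt")); wm(S, file.path(dir, "s.txt"))
  writeLines(as.character(c(1, 1, 2, 3, 3)), file.path(dir, "map.txt"))
  m <- read_electronic_model(file.path(dir, "h.txt"), file.path(dir, "s.txt"),
                             file.path(dir, "map.txt"), z = c(2, 1, 2))
  expect_equal(m$H, H, tolerance = 1e-12)
  expect_equal(m$S, S, tolerance = 1e-12)
  expect_equal(m$n_electrons, 5)
  cr <- mulliken_charges(solve_electronic(m), m)
  expect_equal(sum(cr$charge), 0, tolerance = 1e-8)
  # invalid overlap is rejected
  expect_error(electronic_model(H, -diag(M), 1:M, rep(1, M)),
               "not positive-definite")
})
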