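# shared small fixtures and independent oracles

# independent honeycomb site enumeration: explicit double loop over lattice
# sites, same half-open [0, l - 0.01) crop convention as the builder
oracle_honeycomb_count <- function(lx, ly, b = 1.42) {
  a <- sqrt(3) * b
  count <- 0L
  i <- 0L
  repeat {
    x0 <- i * a
    if (x0 >= lx - 1e-2) break
    for (xoff in c(0, a / 2)) {
      x <- x0 + xoff
      if (x >= lx - 1e-2) next
      zoffs <- if (xoff == 0) c(0, b) else c(1.5 * b, 2.5 * b)
      j <- 0L
      repeat {
        z0 <- j * 3 * b
        if (z0 >= ly - 1e-2) break
        for (zoff in zoffs) {
          if (z0 + zoff < ly - 1e-2) count <- count + 1L
        }
        j <- j + 1L
      }
    }
    i <- i + 1L
  }
  count
}

# a small random but valid bonded chain (no H-H bonds)
random_chain <- function(n = 10L, seed = 1L) {
  set.seed(seed)
  el <- sample(c("C", "C", "C", "O", "N"), n, replace = TRUE)
  pos <- matrix(rnorm(3 * n, sd = 0.3), ncol = 3) + cbind(1.45 * seq_len(n), 0, 0)
  structure_new(el, pos, bonds = cbind(seq_len(n - 1L), 2:n))
}

# minimal three-group composite: two one-atom "sheets" and one one-atom
# "lipid", pairwise at distance d
triad_composite <- function(d) {
  structure_new(rep("C", 3),
                rbind(c(0, 0, 0), c(d, 0, 0), c(d / 2, 0, d * sqrt(3) / 2)),
                groups = c("upper_graphene", "lower_graphene", "lipid_1"))
}

# independent term-by-term energy re-summation (R implementation, no reuse of
# the C++ path): harmonic bonds/angles, cosine torsions, LJ with exclusions
oracle_energy <- function(s, params) {
  n <- n_atoms(s)
  types <- atom_types(s)
  key <- function(a, b) paste(sort(c(a, b)), collapse = "-")
  nb <- lapply(seq_len(n), function(i)
    c(s$bonds[s$bonds[, 1] == i, 2], s$bonds[s$bonds[, 2] == i, 1]))
  e <- 0
  for (m in seq_len(nrow(s$bonds))) {
    i <- s$bonds[m, 1]; j <- s$bonds[m, 2]
    pr <- params$bonds[[key(types[i], types[j])]]
    r <- sqrt(sum((s$positions[i, ] - s$positions[j, ])^2))
    e <- e + pr[1] * (r - pr[2])^2
  }
  for (j in seq_len(n)) {
    ns <- sort(nb[[j]])
    if (length(ns) < 2) next
    pr <- params$angles[[types[j]]]
    cmb <- utils::combn(ns, 2)
    for (m in seq_len(ncol(cmb))) {
      u <- s$positions[cmb[1, m], ] - s$positions[j, ]
      v <- s$positions[cmb[2, m], ] - s$positions[j, ]
      th <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
      e <- e + pr[1] * (th - pr[2] * pi / 180)^2
    }
  }
  tors <- list()
  for (m in seq_len(nrow(s$bonds))) {
    j <- s$bonds[m, 1]; k <- s$bonds[m, 2]
    for (i in setdiff(nb[[j]], k)) for (l in setdiff(nb[[k]], j)) {
      if (i == l) next
      pr <- params$torsions[[key(types[j], types[k])]]
      if (is.null(pr)) pr <- params$torsions[["*-*"]]
      b1 <- s$positions[j, ] - s$positions[i, ]
      b2 <- s$positions[k, ] - s$positions[j, ]
      b3 <- s$positions[l, ] - s$positions[k, ]
      cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
      n1 <- cr(b1, b2); n2 <- cr(b2, b3)
      phi <- atan2(sum(cr(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
      e <- e + pr[1] / 2 * (1 + cos(pr[2] * phi - pr[3] * pi / 180))
      tors[[length(tors) + 1L]] <- sort(c(i, l))
    }
  }
  excl <- list()
  for (m in seq_len(nrow(s$bonds))) excl[[m]] <- sort(s$bonds[m, ])
  for (j in seq_len(n)) {
    ns <- sort(nb[[j]])
    if (length(ns) >= 2) {
      cmb <- utils::combn(ns, 2)
      for (m in seq_len(ncol(cmb))) excl[[length(excl) + 1L]] <- cmb[, m]
    }
  }
  exkey <- unique(vapply(excl, paste, character(1), collapse = "-"))
  t14key <- setdiff(unique(vapply(tors, paste, character(1), collapse = "-")),
                    exkey)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- paste(c(i, j), collapse = "-")
    if (k %in% exkey) next
    scale <- if (k %in% t14key) params$scale14 else 1
    r2 <- sum((s$positions[i, ] - s$positions[j, ])^2)
    if (r2 >= params$cutoff^2) next
    sij <- (params$vdw[[types[i]]][2] + params$vdw[[types[j]]][2]) / 2
    eij <- sqrt(params$vdw[[types[i]]][1] * params$vdw[[types[j]]][1])
    s6 <- (sij^2 / r2)^3
    e <- e + scale * 4 * eij * (s6^2 - s6)
  }
  e
}

# the scaled-down study system: one supercell, short capped (16,0) tube,
# forward stroke to +4.4 Angstrom (the depth at which the paper's loading
# regime is well developed), full retraction; cached because two acceptance
# checks share it
scaled_run_cache <- new.env(parent = emptyenv())
scaled_indentation_run <- function() {
  if (!is.null(scaled_run_cache$traj)) return(scaled_run_cache$traj)
  comp <- assemble_supercell()
  tip <- build_capped_cnt(tip_spec(n = 16, target_length = 12))
  sc <- place_tip(comp, tip, gap = 4.1)
  traj <- suppressWarnings(run_indentation(
    sc,
    protocol_config(max_tip_coord = 4.4, retract_to = -4.1),
    default_ffparams(),
    mconfig = minimizer_config(max_iterations = 250),
    mconfig_initial = minimizer_config(max_iterations = 2000)))
  scaled_run_cache$traj <- traj
  traj
}
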