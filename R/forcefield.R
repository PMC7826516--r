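#' Default force-field parameter set
#'
#' A compact AMBER-style parameter table for C/H/N/O/P with GAFF-like
#' magnitudes.  Atom types are `CA` (carbon with no bonded hydrogen: graphene,
#' nanotube, carbonyl), `CT` (carbon with bonded hydrogen), and the bare
#' element symbols `H`, `N`, `O`, `P`.  Units: force constants kcal/mol/A^2
#' (bonds) and kcal/mol/rad^2 (angles), lengths Angstrom, angles degrees in
#' the table (converted to radians internally), torsion barriers kcal/mol.
#'
#' Bonds and angles must have an explicit entry for every type combination
#' present, otherwise evaluation fails loudly; torsions fall back to the
#' documented wildcard entry `*-*`.  Electrostatics are off by default
#' (`coulomb_k = 0`); set `coulomb_k = 332.0637` and supply per-atom charges
#' to [compute_energy()] to enable fixed-charge Coulomb with the same cutoff.
#'
#' @param cutoff nonbonded cutoff, Angstrom (plain truncation).
#' @param scale14 scaling of 1-4 nonbonded pairs.
#' @return an `FFParams` list.
#' @export
default_ffparams <- function(cutoff = 12.0, scale14 = 0.5) {
  params <- list(
    version = "nanoindent-ff-1",
    bonds = list(   # k (kcal/mol/A^2), r0 (A)
      "CA-CA" = c(469, 1.42), "CA-CT" = c(410, 1.51), "CT-CT" = c(310, 1.526),
      "CT-H" = c(340, 1.09), "CA-H" = c(367, 1.08),
      "CT-O" = c(320, 1.41), "CA-O" = c(450, 1.30),
      "CT-N" = c(367, 1.47), "CA-N" = c(448, 1.40),
      "O-P" = c(230, 1.58), "H-O" = c(553, 0.96), "H-N" = c(434, 1.01),
      "N-O" = c(400, 1.40), "O-O" = c(300, 1.48), "N-N" = c(350, 1.40)
    ),
    angles = list(  # by center type: k (kcal/mol/rad^2), theta0 (deg)
      "CA" = c(63, 120), "CT" = c(50, 109.47), "N" = c(50, 109.47),
      "O" = c(60, 113), "P" = c(45, 109.47), "H" = c(35, 109.47)
    ),
    torsions = list(  # by central bond type: V (kcal/mol), n, gamma (deg)
      "CA-CA" = c(5.0, 2, 180), "CT-CT" = c(1.4, 3, 0),
      "*-*" = c(1.0, 3, 0)
    ),
    vdw = list(     # eps (kcal/mol), sigma (A); Lorentz-Berthelot combining
      "CA" = c(0.086, 3.40), "CT" = c(0.1094, 3.40), "H" = c(0.0157, 2.65),
      "N" = c(0.17, 3.25), "O" = c(0.21, 2.96), "P" = c(0.20, 3.74)
    ),
    cutoff = cutoff, scale14 = scale14, coulomb_k = 0
  )
  class(params) <- "FFParams"
  params
}

#' Assign force-field atom types
#'
#' Carbon is split into `CA` (no bonded hydrogen: aromatic / graphitic /
#' carbonyl) and `CT` (aliphatic, at least one bonded H); other elements map
#' to their symbol.
#'
#' @param s a `Structure`.
#' @return character vector of per-atom types.
#' @export
atom_types <- function(s) {
  types <- s$elements
  if (any(s$elements == "C") && nrow(s$bonds)) {
    hasH <- rep(FALSE, n_atoms(s))
    isH1 <- s$elements[s$bonds[, 1L]] == "H"
    isH2 <- s$elements[s$bonds[, 2L]] == "H"
    hasH[s$bonds[isH2, 1L]] <- TRUE
    hasH[s$bonds[isH1, 2L]] <- TRUE
    types[s$elements == "C"] <- ifelse(hasH[s$elements == "C"], "CT", "CA")
  } else {
    types[s$elements == "C"] <- "CA"
  }
  types
}

pair_key <- function(t1, t2) {
  paste(pmin(t1, t2), pmax(t1, t2), sep = "-")
}

lookup_pair <- function(table, key, what, atoms) {
  hit <- table[key]
  miss <- vapply(hit, is.null, logical(1))
  if (any(miss)) {
    first <- which(miss)[1L]
    stop(sprintf("missing %s parameter '%s' (atoms %s)", what, key[first],
                 paste(atoms[first, ], collapse = "-")), call. = FALSE)
  }
  hit
}

#' Precompute the bonded topology and parameter assignment
#'
#' Enumerates angles (all neighbour pairs at each center) and proper torsions
#' (around every bond) from the bond list, assigns parameters by atom type,
#' and builds the nonbonded exclusion (1-2, 1-3) and scaled 1-4 pair lists.
#' The result is reused across evaluations while the topology is unchanged —
#' the minimizer and the indentation driver call this once.
#'
#' @param s a `Structure`.
#' @param params an `FFParams` object.
#' @param charges optional per-atom charges (e); enables Coulomb when
#'   `params$coulomb_k != 0`.
#' @return an `FFTopology` list consumed by [ff_eval()].
#' @export
ff_topology <- function(s, params = default_ffparams(), charges = NULL) {
  stopifnot(inherits(s, "Structure"))
  n <- n_atoms(s)
  types <- atom_types(s)
  bonds <- s$bonds
  nb <- vector("list", n)
  if (nrow(bonds)) {
    for (m in seq_len(nrow(bonds))) {
      i <- bonds[m, 1L]; j <- bonds[m, 2L]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  # bonds
  if (nrow(bonds)) {
    bkey <- pair_key(types[bonds[, 1L]], types[bonds[, 2L]])
    bp <- lookup_pair(params$bonds, bkey, "bond", bonds)
    bk <- vapply(bp, `[`, numeric(1), 1L)
    br0 <- vapply(bp, `[`, numeric(1), 2L)
  } else bk <- br0 <- numeric(0)
  # angles
  ai <- aj <- ak <- integer(0)
  for (j in seq_len(n)) {
    nbs <- nb[[j]]
    if (length(nbs) >= 2L) {
      cmb <- utils::combn(sort(nbs), 2L)
      ai <- c(ai, cmb[1L, ]); aj <- c(aj, rep(j, ncol(cmb))); ak <- c(ak, cmb[2L, ])
    }
  }
  if (length(aj)) {
    ap <- params$angles[types[aj]]
    miss <- vapply(ap, is.null, logical(1))
    if (any(miss))
      stop(sprintf("missing angle parameter for center type '%s' (atom %d)",
                   types[aj[which(miss)[1L]]], aj[which(miss)[1L]]), call. = FALSE)
    akf <- vapply(ap, `[`, numeric(1), 1L)
    at0 <- vapply(ap, `[`, numeric(1), 2L) * pi / 180
  } else akf <- at0 <- numeric(0)
  # torsions around each bond
  ti <- tj <- tk <- tl <- integer(0)
  if (nrow(bonds)) {
    for (m in seq_len(nrow(bonds))) {
      j <- bonds[m, 1L]; k <- bonds[m, 2L]
      is <- setdiff(nb[[j]], k); ls <- setdiff(nb[[k]], j)
      if (length(is) && length(ls)) {
        grid <- expand.grid(i = is, l = ls)
        grid <- grid[grid$i != grid$l, , drop = FALSE]   # exclude 3-rings
        if (nrow(grid)) {
          ti <- c(ti, grid$i); tj <- c(tj, rep(j, nrow(grid)))
          tk <- c(tk, rep(k, nrow(grid))); tl <- c(tl, grid$l)
        }
      }
    }
  }
  if (length(tj)) {
    tkey <- pair_key(types[tj], types[tk])
    tp <- params$torsions[tkey]
    fb <- params$torsions[["*-*"]]
    tp <- lapply(seq_along(tp), function(m)
      if (is.null(tp[[m]])) fb else tp[[m]])
    if (any(vapply(tp, is.null, logical(1))))
      stop("missing torsion parameter and no '*-*' fallback", call. = FALSE)
    tv <- vapply(tp, `[`, numeric(1), 1L)
    tnn <- as.integer(vapply(tp, `[`, numeric(1), 2L))
    tgg <- vapply(tp, `[`, numeric(1), 3L) * pi / 180
  } else { tv <- tgg <- numeric(0); tnn <- integer(0) }
  # exclusions: 1-2, 1-3; 1-4 pairs scaled
  ex <- matrix(integer(0), ncol = 2L)
  if (nrow(bonds)) ex <- bonds
  if (length(aj)) ex <- rbind(ex, cbind(ai, ak))
  if (nrow(ex)) {
    ex <- unique(cbind(pmin(ex[, 1L], ex[, 2L]), pmax(ex[, 1L], ex[, 2L])))
  }
  p14 <- matrix(integer(0), ncol = 2L)
  if (length(tj)) {
    p14 <- unique(cbind(pmin(ti, tl), pmax(ti, tl)))
    exkey <- ex[, 1L] * (n + 1) + ex[, 2L]
    p14 <- p14[!(p14[, 1L] * (n + 1) + p14[, 2L]) %in% exkey, , drop = FALSE]
  }
  # vdW
  vp <- params$vdw[types]
  miss <- vapply(vp, is.null, logical(1))
  if (any(miss))
    stop(sprintf("missing vdW parameter for type '%s' (atom %d)",
                 types[which(miss)[1L]], which(miss)[1L]), call. = FALSE)
  epsv <- vapply(vp, `[`, numeric(1), 1L)
  sigv <- vapply(vp, `[`, numeric(1), 2L)
  if (is.null(charges)) charges <- numeric(0)
  out <- list(n = n, types = types,
              bi = bonds[, 1L] - 1L, bj = bonds[, 2L] - 1L, bk = bk, br0 = br0,
              ai = ai - 1L, aj = aj - 1L, ak = ak - 1L, akf = akf, at0 = at0,
              ti = ti - 1L, tj = tj - 1L, tk = tk - 1L, tl = tl - 1L,
              tv = tv, tn = tnn, tg = tgg,
              eps = epsv, sig = sigv,
              exi = ex[, 1L] - 1L, exj = ex[, 2L] - 1L,
              p14i = p14[, 1L] - 1L, p14j = p14[, 2L] - 1L,
              scale14 = params$scale14, cutoff = params$cutoff,
              q = as.numeric(charges), coulomb_k = params$coulomb_k)
  class(out) <- "FFTopology"
  out
}

#' Evaluate energy (and gradient) for a fixed topology
#'
#' Low-level entry point: positions change, topology does not.
#'
#' @param topo an `FFTopology` from [ff_topology()].
#' @param positions n x 3 coordinate matrix, Angstrom.
#' @param gradient also compute the analytic gradient?
#' @return list with `total`, per-term totals, `per_atom` partition and
#'   (optionally) `gradient` (dE/dx, kcal/mol/A).
#' @export
ff_eval <- function(topo, positions, gradient = FALSE) {
  stopifnot(inherits(topo, "FFTopology"), nrow(positions) == topo$n)
  ff_eval_cpp(positions,
              topo$bi, topo$bj, topo$bk, topo$br0,
              topo$ai, topo$aj, topo$ak, topo$akf, topo$at0,
              topo$ti, topo$tj, topo$tk, topo$tl, topo$tv, topo$tn, topo$tg,
              topo$eps, topo$sig, topo$exi, topo$exj,
              topo$p14i, topo$p14j, topo$scale14, topo$cutoff,
              topo$q, topo$coulomb_k, gradient)
}

#' Compute the molecular-mechanics energy with per-atom partition
#'
#' Standard harmonic bond and angle terms, cosine torsions, and 12-6
#' Lennard-Jones with 1-2/1-3 exclusion and scaled 1-4 pairs, truncated at
#' the cutoff.  The per-atom partition splits every term equally among its
#' participants (bond 1/2 each, angle 1/3, torsion 1/4, nonbonded pair 1/2),
#' so the partition sums exactly to the total.
#'
#' @param s a `Structure` with bond topology.
#' @param params an `FFParams` object.
#' @param charges optional per-atom charges (e).
#' @return an `EnergyReport`: list with `total`, `terms` (named per-term
#'   totals) and `per_atom` (kcal/mol).
#' @export
compute_energy <- function(s, params = default_ffparams(), charges = NULL) {
  topo <- ff_topology(s, params, charges)
  ev <- ff_eval(topo, s$positions, gradient = FALSE)
  out <- list(total = ev$total,
              terms = c(bond = ev$bond, angle = ev$angle, torsion = ev$torsion,
                        vdw = ev$vdw, coulomb = ev$coulomb),
              per_atom = ev$per_atom)
  class(out) <- "EnergyReport"
  out
}

#' @export
print.EnergyReport <- function(x, ...) {
  cat(sprintf("EnergyReport: total %.4f kcal/mol\n", x$total))
  print(round(x$terms, 4))
  invisible(x)
}

#' Analytic forces
#'
#' Negative gradient of [compute_energy()] with respect to the Cartesian
#' coordinates.
#'
#' @inheritParams compute_energy
#' @return n x 3 matrix of forces, kcal/mol/A.
#' @export
compute_forces <- function(s, params = default_ffparams(), charges = NULL) {
  topo <- ff_topology(s, params, charges)
  ev <- ff_eval(topo, s$positions, gradient = TRUE)
  -ev$gradient
}

#' Energy of a subsystem evaluated in isolation
#'
#' Drops all cross-subset interactions: the subset is extracted with its
#' internal bonds at its current coordinates and evaluated alone.  This is
#' the isolated-part energy entering the adhesion decomposition.
#'
#' @param s a `Structure`.
#' @param subset non-empty integer vector of atom indices.
#' @param params an `FFParams` object.
#' @return energy, kcal/mol.
#' @export
subsystem_energy <- function(s, subset, params = default_ffparams()) {
  if (length(subset) == 0L) stop("empty atom subset")
  compute_energy(subset_structure(s, subset), params)$total
}

#' Write a force-field parameter file
#'
#' Structured key-value text with a versioned header; read back with
#' [read_ffparams()].
#'
#' @param params an `FFParams` object.
#' @param path output file path.
#' @export
write_ffparams <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# ffparams", params$version),
               sprintf("cutoff %.6g", params$cutoff),
               sprintf("scale14 %.6g", params$scale14),
               sprintf("coulomb_k %.6g", params$coulomb_k)), con)
  for (sec in c("bonds", "angles", "torsions", "vdw")) {
    writeLines(paste0("[", sec, "]"), con)
    tab <- params[[sec]]
    for (key in names(tab))
      writeLines(paste(key, paste(signif(tab[[key]], 10), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a force-field parameter file
#' @param path file written by [write_ffparams()].
#' @return an `FFParams` object.
#' @export
read_ffparams <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# ffparams ", lines[1L]))
    stop("not a recognized parameter file (missing versioned header)")
  params <- list(version = sub("^# ffparams ", "", lines[1L]),
                 bonds = list(), angles = list(), torsions = list(),
                 vdw = list(), cutoff = 12, scale14 = 0.5, coulomb_k = 0)
  sec <- NULL
  for (ln in lines[-1L]) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^\\[", ln)) { sec <- gsub("\\[|\\]", "", ln); next }
    parts <- strsplit(ln, "\\s+")[[1L]]
    if (is.null(sec)) {
      params[[parts[1L]]] <- as.numeric(parts[2L])
    } else {
      params[[sec]][[parts[1L]]] <- as.numeric(parts[-1L])
    }
  }
  class(params) <- "FFParams"
  params
}
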