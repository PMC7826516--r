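#' Composite supercell specification
#'
#' Geometry of the repeating unit: two graphene flakes with two DPPC molecules
#' between them.  Defaults reproduce the study system: 25.5 x 35.51 Angstrom
#' flakes, lipid centers 6.23 Angstrom from each sheet plane, and a per-sheet
#' atom budget of 309 so the supercell holds 618 graphene + 260 lipid = 878
#' atoms.
#'
#' @param flake_lx,flake_ly flake extents, Angstrom.
#' @param lipid_distance lipid-center-to-sheet-plane distance, Angstrom.
#' @param n_lipids lipids per supercell.
#' @param tiling integer pair, film-fragment tiling (used by callers).
#' @param bond_length_cc C-C bond length, Angstrom.
#' @param sheet_atoms per-sheet atom budget; outermost atoms are trimmed
#'   symmetrically until each flake holds this many atoms. `NULL` keeps the
#'   full ideal-lattice crop.
#' @return a `CompositeSpec` list.
#' @export
composite_spec <- function(flake_lx = 25.5, flake_ly = 35.51,
                           lipid_distance = 6.23, n_lipids = 2L,
                           tiling = c(3L, 3L), bond_length_cc = 1.42,
                           sheet_atoms = 309L) {
  stopifnot(flake_lx > 0, flake_ly > 0, lipid_distance > 0,
            n_lipids >= 0, all(tiling >= 1L), bond_length_cc > 0)
  out <- list(flake_lx = flake_lx, flake_ly = flake_ly,
              lipid_distance = lipid_distance, n_lipids = as.integer(n_lipids),
              tiling = as.integer(tiling), bond_length_cc = bond_length_cc,
              sheet_atoms = if (is.null(sheet_atoms)) NULL else as.integer(sheet_atoms))
  class(out) <- "CompositeSpec"
  out
}

#' Nanotube tip specification
#'
#' @param n zigzag chiral index; the tube is (n, 0) with radius
#'   n * 2.46 / (2 pi) Angstrom.
#' @param target_length total axial extent including the cap, Angstrom.
#' @param cap close one end with a hemispherical cap?
#' @param initial_gap tip-edge-to-sheet distance at scene construction,
#'   Angstrom.
#' @return a `TipSpec` list.
#' @export
tip_spec <- function(n = 16L, target_length = 50.62, cap = TRUE,
                     initial_gap = 4.1) {
  if (n < 3L) stop("zigzag index n must be >= 3")
  stopifnot(target_length > 0, initial_gap > 0)
  out <- list(n = as.integer(n), target_length = target_length,
              cap = isTRUE(cap), initial_gap = initial_gap)
  class(out) <- "TipSpec"
  out
}

# Honeycomb sites of a rectangular graphene patch in the x-z plane.
# Rectangular 4-atom cell: a = sqrt(3) * b along x (zigzag), 3 * b along z,
# with b the C-C bond length.  Half-open crop [0, lx) x [0, ly) with a 0.01 A
# guard: the conventional lattice constant 2.46 is a rounding of
# sqrt(3) * 1.42 = 2.4595, and without the guard a 2.46-wide request would
# admit a fifth lattice column.
honeycomb_sites <- function(lx, ly, b) {
  a <- sqrt(3) * b            # 2.46 for b = 1.42
  cz <- 3 * b                 # 4.26
  basis <- rbind(c(0, 0), c(0, b), c(a / 2, 1.5 * b), c(a / 2, 2.5 * b))
  nx <- ceiling(lx / a) + 1L
  nz <- ceiling(ly / cz) + 1L
  ij <- expand.grid(i = 0L:(nx - 1L), j = 0L:(nz - 1L))
  xs <- rep(ij$i * a, each = 4L) + basis[, 1L]
  zs <- rep(ij$j * cz, each = 4L) + basis[, 2L]
  keep <- xs > -1e-6 & xs < lx - 1e-2 & zs > -1e-6 & zs < ly - 1e-2
  cbind(xs[keep], zs[keep])
}

#' Build a rectangular graphene flake
#'
#' Crops an ideal honeycomb lattice (C-C bond `bond_length`) to an
#' `lx` x `ly` rectangle in the x-z plane (sheet normal along y, the
#' indentation axis) and recenters the centroid at the origin.  Edges are left
#' unterminated.
#'
#' @param lx,ly flake extents, Angstrom; at least one honeycomb unit
#'   (2.46 x 4.26 at bond 1.42).
#' @param bond_length C-C bond length, Angstrom.
#' @param group group label assigned to all atoms.
#' @return a `Structure` of carbon atoms with perceived first-neighbour bonds.
#' @export
build_graphene_flake <- function(lx, ly, bond_length = 1.42,
                                 group = "upper_graphene") {
  a <- sqrt(3) * bond_length
  if (lx < a - 1e-9 || ly < 3 * bond_length - 1e-9)
    stop("flake dimensions below one honeycomb unit (",
         round(a, 2), " x ", round(3 * bond_length, 2), " Angstrom)")
  xz <- honeycomb_sites(lx, ly, bond_length)
  pos <- cbind(xz[, 1L], 0, xz[, 2L])
  pos <- sweep(pos, 2L, colMeans(pos), "-")
  bonds <- perceive_bonds(pos, bond_length)
  structure_new(rep("C", nrow(pos)), pos, groups = rep(group, nrow(pos)),
                bonds = bonds)
}

#' Build a capped zigzag carbon nanotube tip
#'
#' Rolls a honeycomb lattice into an (n, 0) tube of radius n * 2.46 / (2 pi),
#' axis along y.  When `cap = TRUE` the lattice is continued past the lower
#' end and projected, arc-length preserving, onto a hemisphere of the tube
#' radius; crowded near-pole sites are pruned by a minimum-distance filter.
#' The axial extent (cap included) equals `target_length` to within one bond
#' length.  The open upper end is left unterminated.  All atoms carry group
#' `tip` and are flagged frozen (the tip is rigid in every protocol).
#'
#' @param spec a [tip_spec()].
#' @param bond_length C-C bond length, Angstrom.
#' @return a `Structure` with the cap (if any) at the minimum-y end.
#' @export
build_capped_cnt <- function(spec = tip_spec(), bond_length = 1.42) {
  stopifnot(inherits(spec, "TipSpec"))
  n <- spec$n
  b <- bond_length
  a <- sqrt(3) * b
  r <- n * a / (2 * pi)
  cz <- 3 * b
  cap_arc <- if (spec$cap) pi * r / 2 else 0
  tube_len <- spec$target_length - (if (spec$cap) r else 0)
  if (tube_len <= 0) stop("target_length shorter than the cap radius")
  basis <- rbind(c(0, 0), c(0, b), c(a / 2, 1.5 * b), c(a / 2, 2.5 * b))
  ncell_ax <- ceiling((tube_len + cap_arc) / cz) + 2L
  ij <- expand.grid(i = 0L:(n - 1L), j = 0L:(ncell_ax - 1L))
  xs <- rep(ij$i * a, each = 4L) + basis[, 1L]
  zs <- rep(ij$j * cz, each = 4L) + basis[, 2L] - cap_arc
  phi <- 2 * pi * xs / (n * a)
  ax <- zs                       # axial coordinate; negative part becomes cap
  rad <- rep(r, length(ax))
  y <- ax
  if (spec$cap) {
    onc <- ax < 0
    theta <- pmin(-ax[onc] / r, pi / 2)   # angle below the cap base
    y[onc] <- -r * sin(theta)
    rad[onc] <- r * cos(theta)
  }
  pos <- cbind(rad * cos(phi), y, rad * sin(phi))
  # prune near-pole crowding (deterministic: keep the earliest atom)
  if (spec$cap) {
    ord <- order(-pos[, 2L])      # top first so cap atoms are pruned last
    pos <- pos[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(pos))
    capish <- which(pos[, 2L] < -0.1)
    if (length(capish) > 1L) {
      for (k in seq_along(capish)[-1L]) {
        ik <- capish[k]
        prev <- capish[seq_len(k - 1L)][keep[capish[seq_len(k - 1L)]]]
        if (length(prev)) {
          dmin <- min(sqrt(rowSums(sweep(pos[prev, , drop = FALSE], 2L,
                                         pos[ik, ], "-")^2)))
          if (dmin < 0.9) keep[ik] <- FALSE
        }
      }
    }
    pos <- pos[keep, , drop = FALSE]
  }
  # trim the open end so the measured axial extent matches the target
  pos <- pos[pos[, 2L] < min(pos[, 2L]) + spec$target_length - 1e-6, ,
             drop = FALSE]
  bonds <- perceive_bonds(pos, b, factor = 1.25)
  structure_new(rep("C", nrow(pos)), pos, groups = rep("tip", nrow(pos)),
                frozen = rep(TRUE, nrow(pos)), bonds = bonds)
}

#' Build a DPPC molecule
#'
#' Deterministic internal-coordinate recipe for
#' dipalmitoylphosphatidylcholine, composition C40H80NO8P (130 atoms):
#' choline and phosphate headgroup, glycerol backbone, and two palmitoyl
#' tails in all-anti conformation.  Standard bond lengths are used
#' (C-C 1.54, C-H 1.09, C-O 1.43, P-O 1.60, C-N 1.47 Angstrom); the element
#' composition is exact, the 3-D conformation is a generic starting geometry,
#' not an equilibrium conformer.
#'
#' @param seed integer; seeds a small (0.01 Angstrom) deterministic coordinate
#'   jitter that breaks exact collinearity.  Same seed, same coordinates.
#' @param group group label for all atoms.
#' @return a connected `Structure` with 130 atoms.
#' @export
build_dppc <- function(seed = 1L, group = "lipid_1") {
  el <- character(0)
  pos <- matrix(numeric(0), ncol = 3L)
  bonds <- matrix(integer(0), ncol = 2L)
  add <- function(e, at, bond_to = integer(0)) {
    el <<- c(el, e)
    pos <<- rbind(pos, at)
    for (b in bond_to) bonds <<- rbind(bonds, c(nrow(pos), b))
    nrow(pos)
  }
  # zigzag step along z for bond length L with +-amp alternation in x
  zig_dz <- function(L, amp = 0.4) sqrt(L^2 - (2 * amp)^2)
  amp <- 0.4
  ## head path N -> choline -> phosphate -> glycerol center, one zigzag chain
  ## along +z in the x-z plane (thin along y); both tails branch off it
  path_el <- c("N", "C", "C", "O", "P", "O", "C", "C")
  path_L <- c(1.47, 1.54, 1.43, 1.60, 1.60, 1.43, 1.54)
  ids <- integer(length(path_el))
  z <- 0; x <- amp
  ids[1] <- add(path_el[1], c(x, 0, z))
  for (k in 2:length(path_el)) {
    x <- -x
    z <- z + zig_dz(path_L[k - 1L], amp)
    ids[k] <- add(path_el[k], c(x, 0, z), ids[k - 1L])
  }
  iN <- ids[1]; cc1 <- ids[2]; cc2 <- ids[3]; oph <- ids[4]; iP <- ids[5]
  opg <- ids[6]; g3 <- ids[7]; g2 <- ids[8]
  unit <- function(v) v / sqrt(sum(v^2))
  crossv <- function(a, b) c(a[2L] * b[3L] - a[3L] * b[2L],
                             a[3L] * b[1L] - a[1L] * b[3L],
                             a[1L] * b[2L] - a[2L] * b[1L])
  # tripod of three substituents tetrahedral to direction `away`
  tripod <- function(center, away, L, phase = pi / 2) {
    d <- unit(away)
    u <- unit(crossv(d, if (abs(d[2L]) < 0.9) c(0, 1, 0) else c(1, 0, 0)))
    v <- crossv(d, u)
    lapply(phase + (0:2) * 2 * pi / 3, function(a)
      pos[center, ] + L * (0.3338 * d + 0.9426 * (cos(a) * u + sin(a) * v)))
  }
  ## choline methyls: tetrahedral tripod around N, away from the chain
  mpos <- tripod(iN, pos[iN, ] - pos[cc1, ], 1.47)
  m1 <- add("C", mpos[[1L]], iN)
  m2 <- add("C", mpos[[2L]], iN)
  m3 <- add("C", mpos[[3L]], iN)
  op1 <- add("O", pos[iP, ] + 1.48 * unit(c(0.3, 1.31, 0)), iP)
  op2 <- add("O", pos[iP, ] + 1.48 * unit(c(0.3, -1.31, 0)), iP)
  ## tails: ester linkages branch from the glycerol end (g1, built first) and
  ## center (g2); each bridges to its own zigzag lane, the lanes run parallel
  ## along +z about 4 Angstrom apart
  grow_tail <- function(anchor, sgn) {
    # anchor: glycerol carbon; sgn: -1 (tail 1, -x lane) or +1 (tail 2)
    oe <- add("O", pos[anchor, ] + 1.43 * unit(c(sgn * 1.1, -0.35, 0.9)),
              anchor)
    cct <- add("C", pos[oe, ] + 1.36 * unit(c(sgn * 0.85, 0.35, 1.0)), oe)
    oc <- add("O", pos[cct, ] + 1.23 * unit(c(sgn * 1.1, -0.55, -0.2)), cct)
    chain <- integer(15)
    chain[1L] <- add("C", pos[cct, ] + 1.52 * unit(c(sgn * 0.45, 0.2, 1.4)),
                     cct)
    chain[2L] <- add("C", pos[chain[1L], ] + 1.54 * unit(c(sgn * 0.8, 0, 1.3)),
                     chain[1L])
    lane <- pos[chain[2L], 1L] - sgn * amp
    x <- pos[chain[2L], 1L]; z <- pos[chain[2L], 3L]
    yl <- pos[chain[2L], 2L]
    for (k in 3:15) {
      x <- lane + (lane - x)             # reflect: alternate around the lane
      z <- z + zig_dz(1.54, amp)
      chain[k] <- add("C", c(x, yl, z), chain[k - 1L])
    }
    list(oe = oe, cct = cct, oc = oc, chain = chain)
  }
  g1 <- add("C", pos[g2, ] + 1.54 * unit(c(-1.0, 0.35, 1.05)), g2)
  t1 <- grow_tail(g1, -1)
  t2 <- grow_tail(g2, +1)
  oe1 <- t1$oe; cct1 <- t1$cct; oc1 <- t1$oc; chain1 <- t1$chain
  oe2 <- t2$oe; cct2 <- t2$cct; oc2 <- t2$oc; chain2 <- t2$chain
  ## hydrogens: CH2 pairs out of the backbone plane, methyls tripod-style
  addH2 <- function(c, n1, n2) {         # CH2 with heavy neighbours n1, n2
    away <- pos[c, ] - (pos[n1, ] + pos[n2, ]) / 2
    away[2L] <- 0
    if (sum(away^2) < 1e-4) away <- c(1, 0, 0)
    away <- 0.66 * unit(away)
    add("H", pos[c, ] + away + c(0, 0.867, 0), c)
    add("H", pos[c, ] + away - c(0, 0.867, 0), c)
  }
  addH3 <- function(c, from) {           # CH3, tripod away from `from`
    for (h in tripod(c, pos[c, ] - pos[from, ], 1.09, phase = pi / 6))
      add("H", h, c)
  }
  addH3(m1, iN); addH3(m2, iN); addH3(m3, iN)
  addH2(cc1, iN, cc2); addH2(cc2, cc1, oph)
  addH2(g3, opg, g2)
  add("H", pos[g2, ] + 1.09 * unit(pos[g2, ] -
        (pos[g3, ] + pos[g1, ] + pos[oe2, ]) / 3), g2)
  addH2(g1, g2, oe1)
  for (tl in list(t1, t2)) {
    addH2(tl$chain[1L], tl$cct, tl$chain[2L])
    for (k in 2:14) addH2(tl$chain[k], tl$chain[k - 1L], tl$chain[k + 1L])
    addH3(tl$chain[15L], tl$chain[14L])
  }
  ## deterministic jitter, then center
  set.seed(as.integer(seed))
  pos <- pos + matrix(stats::runif(length(pos), -0.01, 0.01), ncol = 3L)
  pos <- sweep(pos, 2L, colMeans(pos), "-")
  structure_new(el, pos, groups = rep(group, nrow(pos)), bonds = bonds)
}

# Trim a flake to an atom budget by removing outermost atoms (largest
# in-plane distance from the flake centroid; ties broken by index).
trim_flake <- function(flake, budget) {
  n <- n_atoms(flake)
  if (is.null(budget) || budget >= n) return(flake)
  if (budget < 1L) stop("sheet atom budget must be positive")
  ctr <- colMeans(flake$positions)
  d2 <- (flake$positions[, 1L] - ctr[1L])^2 + (flake$positions[, 3L] - ctr[3L])^2
  keep <- order(d2, seq_len(n))[seq_len(budget)]
  out <- subset_structure(flake, sort(keep))
  out
}

#' Assemble the composite supercell
#'
#' Two parallel graphene flakes (sheet planes normal to y) with `n_lipids`
#' DPPC molecules between them, each lipid's geometric center at
#' `lipid_distance` from both sheet planes (sheet separation is therefore
#' twice that).  Lipids are laid flat (long axis in-plane) and offset along x.
#'
#' @param spec a [composite_spec()].
#' @param seed seed forwarded to the lipid builder.
#' @return a `Structure` with groups `upper_graphene`, `lower_graphene`,
#'   `lipid_1..n`.
#' @export
assemble_supercell <- function(spec = composite_spec(), seed = 1L) {
  stopifnot(inherits(spec, "CompositeSpec"))
  up <- build_graphene_flake(spec$flake_lx, spec$flake_ly,
                             spec$bond_length_cc, group = "upper_graphene")
  up <- trim_flake(up, spec$sheet_atoms)
  lo <- up
  lo$groups <- rep("lower_graphene", n_atoms(lo))
  h <- spec$lipid_distance
  up <- translate_structure(up, c(0, h, 0))
  lo <- translate_structure(lo, c(0, -h, 0))
  parts <- list(up, lo)
  if (spec$n_lipids > 0L) {
    xoff <- if (spec$n_lipids == 1L) 0 else
      seq(-spec$flake_lx / 4.2, spec$flake_lx / 4.2, length.out = spec$n_lipids)
    for (k in seq_len(spec$n_lipids)) {
      lip <- build_dppc(seed = seed + k - 1L, group = paste0("lipid_", k))
      lip <- translate_structure(lip, c(xoff[k], 0, 0))
      ymax <- max(abs(lip$positions[, 2L]))
      if (h - ymax < 1.0)
        stop("lipid too large for the interlayer gap (atom within 1 Angstrom ",
             "of a sheet plane)")
      parts[[length(parts) + 1L]] <- lip
    }
  }
  combine_structures(parts)
}

#' Tile a supercell into a film fragment
#'
#' Translates `nx` x `ny` copies of the supercell in-plane (x and z).  The
#' pitch per axis is the supercell's bounding-box extent plus `clearance`, so
#' copies never overlap.  Lipid group labels are re-indexed per copy; sheet
#' labels are merged.  The result is a finite structure, not a periodic cell.
#'
#' @param supercell a `Structure`.
#' @param nx,ny tiling counts, >= 1.
#' @param clearance inter-copy clearance added to the pitch, Angstrom.
#' @return the tiled `Structure` with `nx * ny * n_atoms(supercell)` atoms.
#' @export
tile_fragment <- function(supercell, nx = 3L, ny = 3L, clearance = 1.42) {
  stopifnot(nx >= 1L, ny >= 1L)
  if (nx == 1L && ny == 1L) return(supercell)
  px <- diff(range(supercell$positions[, 1L])) + clearance
  pz <- diff(range(supercell$positions[, 3L])) + clearance
  nlip <- sum(grepl("^lipid_", unique(supercell$groups)))
  parts <- list()
  copy <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    s <- translate_structure(supercell, c((i - 1L) * px, 0, (j - 1L) * pz))
    if (copy > 0L && nlip > 0L) {
      isl <- grepl("^lipid_", s$groups)
      k <- as.integer(sub("^lipid_", "", s$groups[isl]))
      s$groups[isl] <- paste0("lipid_", k + copy * nlip)
    }
    parts[[length(parts) + 1L]] <- s
    copy <- copy + 1L
  }
  out <- combine_structures(parts)
  ctr <- colMeans(out$positions)
  translate_structure(out, c(-ctr[1L], 0, -ctr[3L]))
}

#' Place the tip above the composite
#'
#' Centers the tip laterally over the composite centroid and sets the minimal
#' axial distance between the tip's leading (capped) edge atom and the upper
#' graphene plane to `gap`.  The scene's tip coordinate convention follows the
#' study: `tip_edge_coord` is measured relative to the initial upper-sheet
#' plane, negative above it, so at construction `tip_edge_coord = -gap`.
#'
#' @param composite the film `Structure` (groups `upper_graphene`,
#'   `lower_graphene`, `lipid_*`).
#' @param tip the tip `Structure` (group `tip`, cap toward -y).
#' @param gap initial tip-edge-to-plane distance, Angstrom; must be > 0.
#' @return a `Scene`: list with `structure`, `axis = "y"`, `plane_y` (lab-frame
#'   y of the initial upper-sheet plane) and `tip_edge_coord = -gap`.
#' @export
place_tip <- function(composite, tip, gap = 4.1) {
  if (gap <= 0) stop("tip gap must be positive")
  if (!any(composite$groups == "upper_graphene") ||
      !any(composite$groups == "lower_graphene"))
    stop("composite must contain upper and lower graphene groups")
  if (!any(tip$groups == "tip")) stop("tip structure must carry group 'tip'")
  plane_y <- mean(composite$positions[composite$groups == "upper_graphene", 2L])
  ctr <- colMeans(composite$positions)
  lead <- min(tip$positions[, 2L])
  tip <- translate_structure(tip, c(ctr[1L] - mean(tip$positions[, 1L]),
                                    plane_y + gap - lead,
                                    ctr[3L] - mean(tip$positions[, 3L])))
  tip$frozen <- rep(TRUE, n_atoms(tip))
  sc <- list(structure = combine_structures(composite, tip), axis = "y",
             plane_y = plane_y, tip_edge_coord = -gap)
  class(sc) <- "Scene"
  sc
}

#' @export
print.Scene <- function(x, ...) {
  cat(sprintf("Scene: %d atoms, tip edge at %+.2f Angstrom (axis %s)\n",
              n_atoms(x$structure), x$tip_edge_coord, x$axis))
  invisible(x)
}
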