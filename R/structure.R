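#' Atomistic structure container
#'
#' The universal geometric object of the package: a set of atoms with chemical
#' symbols, Cartesian coordinates, group labels (`upper_graphene`,
#' `lower_graphene`, `lipid_<k>`, `tip`), per-atom frozen flags, and an explicit
#' bond topology.  All coordinates are in Angstrom.
#'
#' @param elements character vector of chemical symbols (C, H, N, O, P).
#' @param positions numeric matrix, n x 3, Angstrom.
#' @param groups character vector of per-atom group labels.
#' @param frozen logical vector; frozen atoms never move during minimization.
#' @param bonds integer matrix, m x 2, 1-based atom indices, i < j.
#'
#' @return An object of class `Structure`.
#' @export
structure_new <- function(elements, positions, groups = NULL, frozen = NULL,
                          bonds = NULL) {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 3L)
    stop("positions must be an n x 3 numeric matrix")
  n <- nrow(positions)
  if (length(elements) != n)
    stop("elements and positions disagree on atom count")
  if (!all(is.finite(positions)))
    stop("positions must be finite")
  allowed <- c("C", "H", "N", "O", "P")
  if (!all(elements %in% allowed))
    stop("element symbols must be one of ", paste(allowed, collapse = ", "))
  if (is.null(groups)) groups <- rep("upper_graphene", n)
  if (length(groups) != n) stop("groups length mismatch")
  if (is.null(frozen)) frozen <- rep(FALSE, n)
  if (length(frozen) != n) stop("frozen length mismatch")
  if (is.null(bonds)) {
    bonds <- matrix(integer(0), ncol = 2L)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    if (nrow(bonds)) {
      if (any(bonds < 1L) || any(bonds > n))
        stop("bond indices out of range")
      if (any(bonds[, 1L] == bonds[, 2L]))
        stop("bonds must be irreflexive")
      bonds <- t(apply(bonds, 1L, sort))
      bonds <- bonds[!duplicated(bonds), , drop = FALSE]
    }
  }
  dimnames(positions) <- NULL
  obj <- list(elements = as.character(elements), positions = positions,
              groups = as.character(groups), frozen = as.logical(frozen),
              bonds = bonds)
  class(obj) <- "Structure"
  obj
}

#' Number of atoms in a Structure
#' @param s a `Structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$positions)

#' Element composition of a Structure
#' @param s a `Structure`.
#' @return named integer vector of element counts.
#' @export
element_counts <- function(s) {
  tab <- table(s$elements)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @export
print.Structure <- function(x, ...) {
  cnt <- element_counts(x)
  cat(sprintf("Structure: %d atoms (%s), %d bonds\n", n_atoms(x),
              paste(sprintf("%s%d", names(cnt), cnt), collapse = " "),
              nrow(x$bonds)))
  cat("  groups:", paste(unique(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Concatenate structures
#'
#' Merges atoms and bond lists; bond indices of later structures are offset.
#' Group labels and frozen flags are preserved verbatim.
#'
#' @param ... `Structure` objects.
#' @return a single merged `Structure`.
#' @export
combine_structures <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "Structure"))
    parts <- parts[[1L]]
  offs <- 0L
  el <- character(0); gr <- character(0); fz <- logical(0)
  pos <- matrix(numeric(0), ncol = 3L)
  bnd <- matrix(integer(0), ncol = 2L)
  for (p in parts) {
    stopifnot(inherits(p, "Structure"))
    el <- c(el, p$elements); gr <- c(gr, p$groups); fz <- c(fz, p$frozen)
    pos <- rbind(pos, p$positions)
    if (nrow(p$bonds)) bnd <- rbind(bnd, p$bonds + offs)
    offs <- offs + n_atoms(p)
  }
  structure_new(el, pos, gr, fz, bnd)
}

#' Rigid translation
#' @param s a `Structure`.
#' @param delta length-3 numeric displacement, Angstrom.
#' @return the translated `Structure`.
#' @export
translate_structure <- function(s, delta) {
  s$positions <- sweep(s$positions, 2L, as.numeric(delta), "+")
  s
}

#' Select a subset of atoms
#'
#' Keeps the given atoms and the bonds internal to the subset (bond indices are
#' remapped).  Used to evaluate subsystems in isolation.
#'
#' @param s a `Structure`.
#' @param idx integer vector of atom indices to keep.
#' @return the sub-`Structure`.
#' @export
subset_structure <- function(s, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L) stop("empty atom subset")
  if (any(idx < 1L) || any(idx > n_atoms(s))) stop("subset index out of range")
  map <- integer(n_atoms(s)); map[idx] <- seq_along(idx)
  keep <- rep(FALSE, nrow(s$bonds))
  if (nrow(s$bonds))
    keep <- s$bonds[, 1L] %in% idx & s$bonds[, 2L] %in% idx
  bnd <- s$bonds[keep, , drop = FALSE]
  if (nrow(bnd)) bnd <- matrix(map[bnd], ncol = 2L)
  structure_new(s$elements[idx], s$positions[idx, , drop = FALSE],
                s$groups[idx], s$frozen[idx], bnd)
}

#' Perceive bonds by first-neighbour distance
#'
#' Connects atom pairs closer than `factor` times the sum-scaled reference
#' length.  Intended for freshly generated lattices where the first-neighbour
#' distance is known; not a general chemical-perception routine.
#'
#' @param positions n x 3 coordinate matrix.
#' @param ref_length reference first-neighbour distance, Angstrom.
#' @param factor tolerance multiplier (default 1.2).
#' @return m x 2 integer bond matrix.
#' @keywords internal
perceive_bonds <- function(positions, ref_length, factor = 1.2) {
  n <- nrow(positions)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  d <- as.matrix(stats::dist(positions))
  hit <- which(upper.tri(d) & d < ref_length * factor & d > 1e-6, arr.ind = TRUE)
  matrix(as.integer(hit), ncol = 2L)
}
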