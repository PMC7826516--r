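#' Electronic model container
#'
#' Hamiltonian/overlap/occupation data for Mulliken population analysis:
#' a symmetric Hamiltonian `H`, a symmetric positive-definite overlap `S`,
#' an orbital-to-atom map, per-atom electron counts `z` (the electrons each
#' atom contributes to the basis), and the total electron count `n_electrons`.
#'
#' @param H M x M symmetric Hamiltonian, energy units.
#' @param S M x M symmetric positive-definite overlap.
#' @param orbital_atom integer vector, length M: owning atom of each orbital.
#' @param z per-atom electron counts.
#' @param n_electrons total electrons (default `sum(z)`, a neutral system).
#' @return an `ElectronicModel` list.
#' @export
electronic_model <- function(H, S = diag(nrow(H)), orbital_atom, z,
                             n_electrons = sum(z)) {
  H <- as.matrix(H); S <- as.matrix(S)
  M <- nrow(H)
  if (ncol(H) != M || any(dim(S) != M)) stop("H and S must be square, same size")
  if (max(abs(H - t(H))) > 1e-12 * max(1, max(abs(H))))
    stop("H must be symmetric")
  if (max(abs(S - t(S))) > 1e-12) stop("S must be symmetric")
  if (length(orbital_atom) != M) stop("orbital-atom map must cover all orbitals")
  if (n_electrons > 2 * M + 1e-9) stop("more electrons than 2 x orbitals")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("overlap matrix is not positive-definite")
  out <- list(H = H, S = S, orbital_atom = as.integer(orbital_atom),
              z = as.numeric(z), n_electrons = n_electrons)
  class(out) <- "ElectronicModel"
  out
}

#' Solve the generalized eigenproblem and fill orbitals
#'
#' Solves `H C = S C E` by symmetric (Loewdin-style Cholesky) orthogonalization
#' and fills molecular orbitals aufbau, two electrons per orbital; a partially
#' filled degenerate frontier shell is split equally over its members.
#'
#' @param model an [electronic_model()].
#' @param degeneracy_tol MO energies closer than this are one shell.
#' @return an `ElectronicState`: `coefficients` (columns, S-orthonormal),
#'   `energies`, `occupations`.
#' @export
solve_electronic <- function(model, degeneracy_tol = 1e-8) {
  stopifnot(inherits(model, "ElectronicModel"))
  L <- t(chol(model$S))                 # S = L L^T
  Hs <- forwardsolve(L, t(forwardsolve(L, model$H)))
  eg <- eigen((Hs + t(Hs)) / 2, symmetric = TRUE)
  ord <- order(eg$values)               # ascending: fill from the bottom
  C <- backsolve(t(L), eg$vectors[, ord, drop = FALSE])
  eps <- eg$values[ord]
  M <- length(eps)
  occ <- numeric(M)
  left <- model$n_electrons
  k <- 1L
  while (left > 1e-12 && k <= M) {
    shell <- which(abs(eps - eps[k]) <= degeneracy_tol & occ == 0)
    cap <- 2 * length(shell)
    fill <- min(left, cap)
    occ[shell] <- fill / length(shell)
    left <- left - fill
    k <- max(shell) + 1L
  }
  out <- list(coefficients = C, energies = eps, occupations = occ)
  class(out) <- "ElectronicState"
  out
}

#' Mulliken charges
#'
#' Density matrix `P = sum_k f_k c_k c_k^T`; gross atomic population
#' `GAP_A = sum_{mu in A} (P S)_{mu mu}`; charge `q_A = z_A - GAP_A`.
#' For a neutral system the charges sum to zero (trace identity
#' `sum_A GAP_A = tr(P S) = N`).
#'
#' @param state an `ElectronicState` from [solve_electronic()].
#' @param model the [electronic_model()] it was solved from.
#' @return a `ChargeReport`: data.frame with `atom`, `gap` (gross
#'   population), `z`, `charge` (e).
#' @export
mulliken_charges <- function(state, model) {
  C <- state$coefficients
  if (nrow(C) != nrow(model$H)) stop("state and model dimensions disagree")
  occ <- state$occupations
  P <- C %*% (occ * t(C))
  gross <- rowSums(P * model$S)         # diag(P S) without forming P S
  natoms <- length(model$z)
  gap <- vapply(seq_len(natoms), function(a)
    sum(gross[model$orbital_atom == a]), numeric(1))
  out <- data.frame(atom = seq_len(natoms), gap = gap, z = model$z,
                    charge = model$z - gap)
  class(out) <- c("ChargeReport", "data.frame")
  out
}

#' Aggregate Mulliken charges by group
#'
#' The Table-2-style bookkeeping of the study: per-group charge sums in the
#' order tip / upper sheet / lipids / lower sheet (groups not present are
#' dropped; extra groups follow alphabetically).
#'
#' @param report a `ChargeReport`.
#' @param grouping character vector: group label per atom; must cover every
#'   atom of the report.
#' @return named numeric vector of group charges, e.
#' @export
group_charges <- function(report, grouping) {
  if (length(grouping) != nrow(report))
    stop("grouping does not cover the atoms of the report")
  g <- grouping
  g[grepl("^lipid_", g)] <- "lipid"
  sums <- tapply(report$charge, g, sum)
  order_pref <- c("tip", "upper_graphene", "lipid", "lower_graphene")
  nm <- c(intersect(order_pref, names(sums)),
          sort(setdiff(names(sums), order_pref)))
  out <- as.numeric(sums[nm])
  names(out) <- nm
  out
}

# per-element defaults of the minimal one-orbital-per-heavy-atom basis;
# the onsite ordering (carbon deepest) makes the phospholipid a net charge
# donor to the graphene sheets, the behaviour seen in the reference
# self-consistent calculations of this composite
tb_defaults <- function() {
  list(onsite = c(C = -8.0, N = -6.5, O = -7.0, P = -5.0),   # eV
       z = c(C = 1, N = 1, O = 2, P = 1),   # electrons contributed per atom
       t0 = -2.7,      # hopping at the reference bond length, eV
       s0 = 0.15,      # overlap at the reference bond length
       d0 = 1.42,      # reference bond length, Angstrom
       decay = 0.45,   # exponential decay length, Angstrom
       cutoff = 4.0)   # interaction cutoff, Angstrom
}

#' Build a toy tight-binding model from a structure
#'
#' Minimal non-self-consistent surrogate for the electronic-structure step:
#' one orbital per heavy atom (hydrogens are not part of the basis), onsite
#' energies per element, and hoppings/overlaps decaying exponentially with
#' interatomic distance, truncated at a cutoff.  Intended for qualitative
#' charge-transfer bookkeeping, not quantitative electronic structure.
#'
#' @param s a `Structure` (heavy-atom count is the orbital count; capped at
#'   `max_orbitals`).
#' @param rules parameter list as in the default (see source); override
#'   entries to tune the surrogate.
#' @param max_orbitals guard against accidentally huge models.
#' @return an [electronic_model()] whose `orbital_atom` indexes the heavy
#'   atoms in structure order; attribute `heavy_atoms` maps orbitals back to
#'   atom indices of `s`.
#' @export
build_toy_tightbinding <- function(s, rules = tb_defaults(),
                                   max_orbitals = 2000L) {
  heavy <- which(s$elements != "H")
  M <- length(heavy)
  if (M < 1L) stop("structure has no heavy atoms")
  if (M > max_orbitals)
    stop("structure too large for the toy tight-binding backend (",
         M, " orbitals > ", max_orbitals, ")")
  el <- s$elements[heavy]
  pos <- s$positions[heavy, , drop = FALSE]
  H <- diag(rules$onsite[el], M)
  S <- diag(1, M)
  cutoff2 <- rules$cutoff^2
  for (i in seq_len(M - 1L)) {
    d2 <- rowSums(sweep(pos[(i + 1L):M, , drop = FALSE], 2L, pos[i, ], "-")^2)
    js <- which(d2 < cutoff2) + i
    for (j in js) {
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      fac <- exp(-(d - rules$d0) / rules$decay)
      H[i, j] <- H[j, i] <- rules$t0 * fac
      S[i, j] <- S[j, i] <- rules$s0 * fac
    }
  }
  model <- electronic_model(H, S, orbital_atom = seq_len(M),
                            z = as.numeric(rules$z[el]))
  attr(model, "heavy_atoms") <- heavy
  model
}

#' Mulliken group charges of a scene via the toy backend
#'
#' Convenience wrapper: builds the tight-binding surrogate over the heavy
#' atoms of a structure, solves it, and aggregates Mulliken charges by the
#' structure's groups.
#'
#' @param s a `Structure`.
#' @param rules tight-binding parameter overrides (see
#'   [build_toy_tightbinding()]).
#' @return list with `report` (per-heavy-atom `ChargeReport`) and `groups`
#'   (named group sums, e).
#' @export
scene_charges <- function(s, rules = tb_defaults()) {
  model <- build_toy_tightbinding(s, rules)
  heavy <- attr(model, "heavy_atoms")
  state <- solve_electronic(model)
  rep <- mulliken_charges(state, model)
  list(report = rep, groups = group_charges(rep, s$groups[heavy]))
}

#' Read an electronic model from plain-text matrix files
#'
#' Dense symmetric matrices in a simple text format: first line the dimension
#' M, then M whitespace-separated rows.  The map file holds one integer per
#' orbital (1-based owning atom) and one `z` value per atom.
#'
#' @param h_path,s_path Hamiltonian and overlap matrix files.
#' @param map_path two-column file: orbital's atom index; first column
#'   orbital atom, one row per orbital.
#' @param z per-atom electron counts (recycled if length 1).
#' @param n_electrons total electrons; default neutral.
#' @return an [electronic_model()].
#' @export
read_electronic_model <- function(h_path, s_path, map_path, z,
                                  n_electrons = NULL) {
  read_mat <- function(path) {
    lines <- readLines(path)
    M <- as.integer(trimws(lines[1L]))
    vals <- scan(text = lines[-1L], quiet = TRUE)
    if (length(vals) != M * M) stop("matrix file ", path, ": expected ",
                                    M * M, " values, got ", length(vals))
    matrix(vals, nrow = M, byrow = TRUE)
  }
  H <- read_mat(h_path)
  S <- read_mat(s_path)
  map <- as.integer(scan(map_path, quiet = TRUE))
  natoms <- max(map)
  z <- rep_len(as.numeric(z), natoms)
  if (is.null(n_electrons)) n_electrons <- sum(z)
  electronic_model(H, S, map, z, n_electrons)
}
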