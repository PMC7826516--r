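#' Indentation protocol configuration
#'
#' Displacement-controlled quasi-static protocol: the rigid tip advances in
#' `step` increments along the indentation axis with a full relaxation of the
#' composite at every step (forward stroke), then retracts the same way
#' (reverse stroke).  Defaults are the study protocol: 0.5 Angstrom steps,
#' forward to tip coordinate +17.4 (the deepest point), retraction back to
#' the starting coordinate.
#'
#' @param step tip displacement per step, Angstrom.
#' @param max_tip_coord deepest tip-edge coordinate reached, Angstrom
#'   (convention: relative to the initial upper-sheet plane, positive below).
#' @param retract_to tip-edge coordinate at which the reverse stroke ends.
#' @param freeze_edges freeze an outer margin of both graphene sheets so the
#'   finite film cannot translate rigidly?
#' @param edge_margin width of the frozen margin, Angstrom.
#' @param record_stress compute per-atom stress maps at every step?
#' @return a `ProtocolConfig` list.
#' @export
protocol_config <- function(step = 0.5, max_tip_coord = 17.4,
                            retract_to = -4.1, freeze_edges = TRUE,
                            edge_margin = 3.0, record_stress = TRUE) {
  stopifnot(step > 0)
  out <- list(step = step, max_tip_coord = max_tip_coord,
              retract_to = retract_to, freeze_edges = isTRUE(freeze_edges),
              edge_margin = edge_margin, record_stress = isTRUE(record_stress))
  class(out) <- "ProtocolConfig"
  out
}

composite_indices <- function(s) which(s$groups != "tip")

lipid_indices <- function(s) which(grepl("^lipid_", s$groups))

#' Adhesion energy between the graphene sheets and the phospholipids
#'
#' Energy decomposition at fixed geometry:
#' `E_ADH = E_TOT - E_DPPC - E_UP - E_LOW`, where `E_TOT` is the energy of
#' the composite (tip excluded), and the other three are the energies of all
#' lipids together, the upper sheet, and the lower sheet, each evaluated in
#' isolation at its current coordinates.  With no cross-group bonds this
#' equals the sum of all cross-group nonbonded interactions; it is negative
#' when the parts attract.
#'
#' @param s a `Structure`; groups `upper_graphene`, `lower_graphene` and
#'   `lipid_*` must partition the composite atoms (a `tip` group, if present,
#'   is excluded).
#' @param params an `FFParams` object.
#' @return kcal/mol.
#' @export
adhesion_energy <- function(s, params = default_ffparams()) {
  comp <- composite_indices(s)
  if (length(comp) == 0L) stop("no composite atoms")
  lip <- lipid_indices(s)
  up <- which(s$groups == "upper_graphene")
  lo <- which(s$groups == "lower_graphene")
  if (length(up) == 0L || length(lo) == 0L)
    stop("grouping must contain non-empty upper and lower graphene sheets")
  if (length(lip) + length(up) + length(lo) != length(comp))
    stop("groups do not partition the composite atoms")
  e_tot <- subsystem_energy(s, comp, params)
  e_up <- subsystem_energy(s, up, params)
  e_lo <- subsystem_energy(s, lo, params)
  e_lip <- if (length(lip)) subsystem_energy(s, lip, params) else 0
  e_tot - e_lip - e_up - e_lo
}

freeze_sheet_edges <- function(s, margin) {
  for (grp in c("upper_graphene", "lower_graphene")) {
    idx <- which(s$groups == grp)
    if (!length(idx)) next
    xs <- s$positions[idx, 1L]; zs <- s$positions[idx, 3L]
    edge <- xs < min(xs) + margin | xs > max(xs) - margin |
            zs < min(zs) + margin | zs > max(zs) - margin
    s$frozen[idx[edge]] <- TRUE
  }
  s
}

#' Run the quasi-static indentation protocol
#'
#' Relaxes the composite at the initial scene (caching the per-atom reference
#' energies that define the zero of the stress maps), then alternates rigid
#' tip displacement and conjugate-gradient relaxation through the forward and
#' reverse strokes.  Each step records the tip coordinate, total energy,
#' adhesion energy, and (optionally) the per-layer maximum local stress.
#' A step whose relaxation does not reach the RMS-gradient tolerance is
#' flagged and the run continues; a non-finite energy aborts.
#'
#' @param scene a `Scene` from [place_tip()].
#' @param protocol a [protocol_config()].
#' @param params an `FFParams` object.
#' @param mconfig a [minimizer_config()].
#' @param mconfig_initial minimizer configuration for the pre-indentation
#'   relaxation (default: `mconfig`); the initial state defines the stress
#'   reference, so it is worth relaxing harder than the warm-started steps.
#' @param stress_params a [stress_params()] used when `record_stress`.
#' @param verbose print one line per step?
#' @return a `Trajectory`: list with `records` (data.frame), `frames`
#'   (relaxed structures per step), `reference` (per-atom reference energies
#'   of the composite), `scene`, and the configs used.
#' @export
run_indentation <- function(scene, protocol = protocol_config(),
                            params = default_ffparams(),
                            mconfig = minimizer_config(),
                            mconfig_initial = NULL,
                            stress_params = NULL, verbose = FALSE) {
  stopifnot(inherits(scene, "Scene"))
  if (protocol$max_tip_coord < scene$tip_edge_coord)
    stop("max_tip_coord must not be above the initial tip coordinate")
  if (is.null(stress_params)) stress_params <- stress_params()
  s <- scene$structure
  tipidx <- which(s$groups == "tip")
  if (!length(tipidx)) stop("scene has no tip atoms")
  s$frozen[tipidx] <- TRUE
  if (protocol$freeze_edges) s <- freeze_sheet_edges(s, protocol$edge_margin)
  comp <- composite_indices(s)
  topo <- ff_topology(s, params)
  comp_struct <- subset_structure(s, comp)
  comp_topo <- ff_topology(comp_struct, params)

  relax_and_record <- function(s, coord, stroke, mc = mconfig) {
    res <- minimize(s, params, mc, topo = topo)
    if (!is.finite(res$energy))
      stop("non-finite energy at tip coordinate ", coord)
    s <- res$structure
    ev_comp <- ff_eval(comp_topo, s$positions[comp, , drop = FALSE])
    e_adh <- adhesion_energy(s, params)
    list(structure = s, energy = res$energy, converged = res$converged,
         iterations = res$iterations, e_comp = ev_comp$total,
         per_atom = ev_comp$per_atom, e_adh = e_adh, coord = coord,
         stroke = stroke)
  }

  coord <- scene$tip_edge_coord
  if (verbose) message("relaxing initial scene ...")
  if (is.null(mconfig_initial)) mconfig_initial <- mconfig
  st <- relax_and_record(s, coord, "forward", mc = mconfig_initial)
  reference <- st$per_atom            # pre-indentation energies: the w0 source
  steps <- list(st)
  s <- st$structure
  advance <- function(s, dy) {
    s$positions[tipidx, 2L] <- s$positions[tipidx, 2L] + dy
    s
  }
  while (coord + protocol$step <= protocol$max_tip_coord + 1e-9) {
    coord <- coord + protocol$step
    s <- advance(s, -protocol$step)   # deeper = smaller lab y
    st <- relax_and_record(s, coord, "forward")
    steps[[length(steps) + 1L]] <- st
    s <- st$structure
    if (verbose)
      message(sprintf("FS %+6.2f  E = %11.3f  E_ADH = %9.3f  %s", coord,
                      st$energy, st$e_adh,
                      if (st$converged) "" else "(not converged)"))
  }
  while (coord - protocol$step >= protocol$retract_to - 1e-9) {
    coord <- coord - protocol$step
    s <- advance(s, protocol$step)
    st <- relax_and_record(s, coord, "reverse")
    steps[[length(steps) + 1L]] <- st
    s <- st$structure
    if (verbose)
      message(sprintf("RS %+6.2f  E = %11.3f  E_ADH = %9.3f  %s", coord,
                      st$energy, st$e_adh,
                      if (st$converged) "" else "(not converged)"))
  }

  comp_s <- subset_structure(steps[[1L]]$structure, comp)
  rec <- data.frame(
    step = seq_along(steps) - 1L,
    stroke = vapply(steps, `[[`, character(1), "stroke"),
    tip_edge_coord = vapply(steps, `[[`, numeric(1), "coord"),
    e_total = vapply(steps, `[[`, numeric(1), "energy"),
    e_adh = vapply(steps, `[[`, numeric(1), "e_adh"),
    converged = vapply(steps, `[[`, logical(1), "converged"),
    iterations = vapply(steps, `[[`, integer(1), "iterations"))
  if (protocol$record_stress) {
    mls_up <- mls_lo <- numeric(length(steps))
    for (k in seq_along(steps)) {
      sm <- local_stress_map(steps[[k]]$per_atom, reference, stress_params,
                             layers = comp_s$groups)
      mls_up[k] <- max_layer_stress(sm, "upper_graphene")$value
      mls_lo[k] <- max_layer_stress(sm, "lower_graphene")$value
    }
    rec$mls_upper <- mls_up
    rec$mls_lower <- mls_lo
  }
  nconv <- sum(!rec$converged)
  if (nconv > 0L)
    warning(nconv, " of ", nrow(rec),
            " relaxations did not reach the RMS-gradient tolerance")
  out <- list(records = rec,
              frames = lapply(steps, `[[`, "structure"),
              per_atom = lapply(steps, `[[`, "per_atom"),
              reference = reference,
              composite = comp_s,
              scene = scene, protocol = protocol,
              stress_params = stress_params)
  class(out) <- "Trajectory"
  out
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d records (%d forward, %d reverse), tip %.1f to %.1f Angstrom\n",
              nrow(x$records), sum(x$records$stroke == "forward"),
              sum(x$records$stroke == "reverse"),
              min(x$records$tip_edge_coord), max(x$records$tip_edge_coord)))
  invisible(x)
}

# strict extrema with plateau handling: runs of equal values are compressed
# and an interior run that beats both neighbours is flagged at its first index
run_extrema <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mins <- maxs <- integer(0)
  if (length(r$values) >= 3L) {
    for (m in 2:(length(r$values) - 1L)) {
      if (r$values[m] < r$values[m - 1L] && r$values[m] < r$values[m + 1L])
        mins <- c(mins, starts[m])
      if (r$values[m] > r$values[m - 1L] && r$values[m] > r$values[m + 1L])
        maxs <- c(maxs, starts[m])
    }
  }
  list(minima = mins, maxima = maxs)
}

#' Detect key points of an indentation trajectory
#'
#' Flags, within each stroke: discrete local minima and maxima of the total
#' energy (strictly below/above both neighbouring values; plateaus are
#' reported at their first index), the step of maximum adhesion magnitude
#' |E_ADH|, and (when stress was recorded) the step of maximum MLS.  Labels
#' are assigned in stroke order (A, B, ...).
#'
#' @param traj a `Trajectory`, or a data.frame with at least `stroke` and
#'   `e_total` columns; needs >= 3 records.
#' @return data.frame with `label`, `step`, `stroke`, `reason`.
#' @export
detect_key_points <- function(traj) {
  rec <- if (inherits(traj, "Trajectory")) traj$records else traj
  if (nrow(rec) < 3L) stop("trajectory too short for key-point detection")
  out <- data.frame(step = integer(0), stroke = character(0),
                    reason = character(0))
  flag <- function(step, stroke, reason)
    out <<- rbind(out, data.frame(step = step, stroke = stroke, reason = reason))
  for (stroke in unique(rec$stroke)) {
    idx <- which(rec$stroke == stroke)
    ex <- run_extrema(rec$e_total[idx])
    for (m in ex$minima) flag(rec$step[idx[m]], stroke, "energy local minimum")
    for (m in ex$maxima) flag(rec$step[idx[m]], stroke, "energy local maximum")
    am <- which.max(abs(rec$e_adh[idx]))
    flag(rec$step[idx[am]], stroke, "maximum |adhesion energy|")
    if ("mls_upper" %in% names(rec)) {
      mls <- pmax(rec$mls_upper[idx], rec$mls_lower[idx])
      flag(rec$step[idx[which.max(mls)]], stroke, "maximum local stress")
    }
  }
  out <- out[order(out$step, out$reason), , drop = FALSE]
  out$label <- LETTERS[seq_len(nrow(out))]
  rownames(out) <- NULL
  out[, c("label", "step", "stroke", "reason")]
}
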