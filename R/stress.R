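#' Unit conversion: kcal/mol/Angstrom^3 to GPa
#'
#' 1 kcal/mol/A^3 = 4184 J / (6.02214076e23) / 1e-30 m^3 = 6.9477 GPa.
#' @export
KCAL_MOL_A3_TO_GPA <- 4184 / 6.02214076e23 / 1e-30 / 1e9

#' Local-stress parameters
#'
#' The per-atom stress is the absolute change in energy volume density,
#' `sigma_i = |w_i - w0_i|` with `w = E / V`, using the spherical atomic
#' volume `V = 4 pi r^3 / 3` of a carbon atom of radius 1.7 Angstrom.
#'
#' @param r atomic radius, Angstrom.
#' @return a `StressParams` list with `r`, `volume` (A^3) and the
#'   kcal/mol/A^3 -> GPa conversion factor.
#' @export
stress_params <- function(r = 1.7) {
  out <- list(r = r, volume = atom_volume(r), to_gpa = KCAL_MOL_A3_TO_GPA)
  class(out) <- "StressParams"
  out
}

#' Spherical atomic volume
#' @param r atomic radius, Angstrom; must be positive.
#' @return 4 pi r^3 / 3, Angstrom^3.
#' @export
atom_volume <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("atomic radius must be a positive number")
  4 * pi * r^3 / 3
}

#' Per-atom local-stress map
#'
#' `sigma_i = |E_i - E0_i| / V_i`, converted to GPa.  `E_i` are the current
#' partitioned per-atom energies, `E0_i` the reference (pre-indentation)
#' energies of the same atoms.
#'
#' @param current per-atom energies, kcal/mol.
#' @param reference per-atom reference energies, kcal/mol; same length and
#'   atom order as `current`.
#' @param params a [stress_params()].
#' @param layers optional per-atom layer/group tags carried into the map.
#' @return a `StressMap`: data.frame with `sigma` (GPa), `e_current`, `e_ref`
#'   and optionally `layer`.
#' @export
local_stress_map <- function(current, reference, params = stress_params(),
                             layers = NULL) {
  if (length(current) != length(reference))
    stop("current and reference energies cover different atom sets")
  sigma <- abs(current - reference) / params$volume * params$to_gpa
  map <- data.frame(atom = seq_along(current), sigma = sigma,
                    e_current = current, e_ref = reference)
  if (!is.null(layers)) {
    if (length(layers) != length(current))
      stop("layer tags cover a different atom set")
    map$layer <- layers
  }
  class(map) <- c("StressMap", "data.frame")
  map
}

#' Maximum local stress within a graphene layer
#'
#' @param map a `StressMap` with a `layer` column.
#' @param layer layer tag, e.g. `"upper_graphene"` or `"lower_graphene"`.
#' @return list with `value` (GPa) and `atom` (index into the map; lowest
#'   index on ties).
#' @export
max_layer_stress <- function(map, layer) {
  if (!"layer" %in% names(map)) stop("stress map carries no layer tags")
  idx <- which(map$layer == layer)
  if (!length(idx)) stop("no atoms in layer '", layer, "'")
  k <- idx[which.max(map$sigma[idx])]
  list(value = map$sigma[k], atom = map$atom[k])
}
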