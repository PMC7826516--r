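#' Write structures to extended XYZ
#'
#' Per-atom columns: element, x, y, z, group, frozen (0/1).  Multiple
#' structures are written as consecutive frames.
#'
#' @param s a `Structure` or a list of them (frames).
#' @param path output path.
#' @export
write_xyz <- function(s, path) {
  frames <- if (inherits(s, "Structure")) list(s) else s
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    stopifnot(inherits(fr, "Structure"))
    writeLines(as.character(n_atoms(fr)), con)
    writeLines("Properties=species:S:1:pos:R:3:group:S:1:frozen:I:1", con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f %s %d", fr$elements,
                       fr$positions[, 1L], fr$positions[, 2L],
                       fr$positions[, 3L], fr$groups,
                       as.integer(fr$frozen)), con)
  }
  invisible(path)
}

#' Read extended XYZ
#'
#' Accepts plain XYZ (element + coordinates) or the extended form written by
#' [write_xyz()].  Positions round-trip to better than 1e-6 Angstrom.
#'
#' @param path input path.
#' @param frames return all frames as a list?  Default returns the first
#'   frame only.
#' @param bonds optional m x 2 bond matrix to attach (XYZ carries no bonds).
#' @return a `Structure`, or a list of them when `frames = TRUE`.
#' @export
read_xyz <- function(path, frames = FALSE, bonds = NULL) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n))
      stop("parse error at line ", i, ": expected an atom count")
    if (i + 1L + n > length(lines))
      stop("parse error at line ", i, ": atom count ", n,
           " exceeds remaining lines")
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    ncol <- lengths(rows)
    if (any(ncol < 4L))
      stop("parse error at line ", i + 1L + which(ncol < 4L)[1L],
           ": expected at least 4 fields")
    el <- vapply(rows, `[`, character(1), 1L)
    pos <- suppressWarnings(
      t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3))))
    if (any(!is.finite(pos)))
      stop("parse error: non-numeric coordinate in frame starting at line ", i)
    gr <- if (all(ncol >= 5L)) vapply(rows, `[`, character(1), 5L) else NULL
    fz <- if (all(ncol >= 6L))
      as.logical(as.integer(vapply(rows, `[`, character(1), 6L))) else NULL
    out[[length(out) + 1L]] <- structure_new(el, pos, gr, fz, bonds)
    i <- i + 2L + n
  }
  if (!length(out)) stop("no frames found in ", path)
  if (frames) out else out[[1L]]
}

#' Write a bond list file
#'
#' Two columns of 0-based atom indices, one bond per line.
#' @param s a `Structure`.
#' @param path output path.
#' @export
write_bonds <- function(s, path) {
  utils::write.table(s$bonds - 1L, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a bond list file (0-based indices)
#' @param path file written by [write_bonds()].
#' @return m x 2 integer matrix of 1-based bond indices.
#' @export
read_bonds <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  matrix(as.integer(m), ncol = 2L) + 1L
}

#' Write a structure as PDB
#'
#' Group tags map to residue names (first 3 characters, upper-cased) and
#' chain identifiers; atom numbering is 1-based as the format requires.
#'
#' @param s a `Structure`.
#' @param path output path.
#' @export
write_pdb <- function(s, path) {
  groups <- unique(s$groups)
  chain <- setNames(rep(LETTERS, length.out = length(groups)), groups)
  resname <- setNames(toupper(substr(gsub("_", "", groups), 1L, 3L)), groups)
  resid <- setNames(seq_along(groups), groups)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n_atoms(s)), s$elements, resname[s$groups], chain[s$groups],
    resid[s$groups], s$positions[, 1L], s$positions[, 2L], s$positions[, 3L],
    s$elements)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write trajectory records as CSV
#' @param traj a `Trajectory`.
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj$records, path, row.names = FALSE)
  invisible(path)
}

#' Export a stress map as CSV
#'
#' One row per atom: index (0-based), element, layer, coordinates, stress.
#'
#' @param map a `StressMap` with layer tags.
#' @param s the `Structure` the map refers to (same atom order).
#' @param path output path.
#' @export
write_stress_csv <- function(map, s, path) {
  stopifnot(nrow(map) == n_atoms(s))
  df <- data.frame(atom = map$atom - 1L, element = s$elements,
                   layer = if ("layer" %in% names(map)) map$layer else s$groups,
                   x = s$positions[, 1L], y = s$positions[, 2L],
                   z = s$positions[, 3L], sigma_gpa = map$sigma)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

run_config_keys <- c("structure", "forcefield", "protocol", "minimizer",
                     "stress", "output_dir", "seed", "log_level")

#' Read a run configuration
#'
#' YAML with top-level keys `structure`, `forcefield`, `protocol`,
#' `minimizer`, `stress`, `output_dir`, `seed`, `log_level`; unknown keys are
#' rejected.  Round-trips losslessly through [write_run_config()].
#'
#' @param path YAML file.
#' @return a `RunConfig` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  class(cfg) <- "RunConfig"
  cfg
}

#' Write a run configuration
#' @param cfg a `RunConfig` (named list restricted to the known keys).
#' @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
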