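## S3 containers: xyz_structure (one geometry + energy) and
## conformer_ensemble (ordered collection sharing one atom sequence).

#' Construct a molecular structure
#'
#' A single molecular geometry: element symbols, Cartesian coordinates in
#' Angstrom, a total energy in kcal/mol, and optional per-structure
#' thermochemical (`g_rrho`) and solvation (`g_solv`) free-energy terms.
#'
#' @param symbols Character vector of element symbols.
#' @param coords Numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param energy Total energy in kcal/mol.
#' @param g_rrho Optional RRHO thermal/entropic correction, kcal/mol.
#' @param g_solv Optional solvation free energy, kcal/mol.
#' @param tag Free-text identifier.
#' @return An object of class `xyz_structure`.
#' @examples
#' s <- xyz_structure(c("O", "H", "H"),
#'                    rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'                    energy = -47763.2)
#' s
#' @export
xyz_structure <- function(symbols, coords, energy,
                          g_rrho = NA_real_, g_solv = NA_real_, tag = "") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("coords must be a numeric N x 3 matrix")
  if (nrow(coords) != length(symbols))
    stop("coords row count (", nrow(coords),
         ") does not match number of atom symbols (", length(symbols), ")")
  if (!is.finite(energy))
    stop("energy must be finite")
  dimnames(coords) <- NULL
  structure(
    list(symbols = as.character(symbols), coords = coords,
         energy = as.numeric(energy), g_rrho = as.numeric(g_rrho),
         g_solv = as.numeric(g_solv), tag = as.character(tag)),
    class = "xyz_structure")
}

#' @export
print.xyz_structure <- function(x, ...) {
  cat(sprintf("<xyz_structure> %d atoms (%s), E = %.4f kcal/mol%s\n",
              length(x$symbols),
              paste(utils::head(unique(x$symbols), 6), collapse = ","),
              x$energy,
              if (nzchar(x$tag)) paste0(" [", x$tag, "]") else ""))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure An `xyz_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) length(structure$symbols)

#' Construct a conformer ensemble
#'
#' An ordered, non-empty collection of [xyz_structure] objects sharing one
#' atom sequence (same element symbols in the same order), plus a sampling
#' temperature and free-text provenance.
#'
#' @param structures List of `xyz_structure` objects.
#' @param temperature Temperature in Kelvin (default 298.15).
#' @param provenance Free text describing the origin of the ensemble.
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(structures, temperature = 298.15,
                               provenance = "") {
  if (!is.list(structures) || length(structures) == 0L)
    stop("ensemble must contain at least one structure")
  ok <- vapply(structures, inherits, logical(1), "xyz_structure")
  if (!all(ok)) stop("all elements must be xyz_structure objects")
  ref <- structures[[1]]$symbols
  for (i in seq_along(structures)) {
    if (!identical(structures[[i]]$symbols, ref))
      stop("inconsistent atom symbols: structure ", i,
           " differs from structure 1")
  }
  structure(
    list(structures = structures, temperature = as.numeric(temperature),
         provenance = as.character(provenance)),
    class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  e <- ensemble_energies(x)
  cat(sprintf(
    "<conformer_ensemble> %d structures x %d atoms, T = %.2f K\n",
    length(x$structures), length(x$structures[[1]]$symbols), x$temperature))
  cat(sprintf("  energies [kcal/mol]: min %.4f, max %.4f (spread %.4f)\n",
              min(e), max(e), max(e) - min(e)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.conformer_ensemble <- function(x) length(x$structures)

#' Extract the total energies of an ensemble
#' @param ensemble A `conformer_ensemble`.
#' @return Numeric vector of energies, kcal/mol, in ensemble order.
#' @export
ensemble_energies <- function(ensemble) {
  vapply(ensemble$structures, `[[`, numeric(1), "energy")
}

#' Per-structure Gibbs free energies of an ensemble
#'
#' G_i = E_i + g_rrho_i + g_solv_i, with absent (NA) terms treated as zero.
#' A warning is emitted when every structure lacks a thermochemical term.
#'
#' @param ensemble A `conformer_ensemble`.
#' @return Numeric vector of Gibbs energies, kcal/mol.
#' @export
ensemble_gibbs <- function(ensemble) {
  vapply(ensemble$structures, function(s)
    gibbs_energy(s$energy, g_rrho = s$g_rrho, g_solv = s$g_solv,
                 warn_missing = FALSE), numeric(1))
}
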