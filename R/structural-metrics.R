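## The two CRE discriminators: minimal RMSD after optimal (proper-rotation)
## superposition, and rotational constants from the principal moments of
## inertia.

#' Minimal RMSD between two structures after optimal superposition
#'
#' Computes the minimum over all rigid motions (translations and proper
#' rotations) of the root-mean-square atomic displacement between two
#' structures with identical atom sequences, via the Kabsch algorithm.
#' The SVD determinant correction restricts the search to proper rotations,
#' so a structure is never superposed onto its mirror image. No atom
#' re-indexing is attempted: ensembles from iterative samplers are
#' index-consistent by construction.
#'
#' @param a,b `xyz_structure` objects with identical atom symbol sequences.
#' @param heavy_only If `TRUE`, hydrogens (and deuterium) are excluded
#'   before superposition. Default `FALSE` (all atoms).
#' @return RMSD in Angstrom (non-negative scalar).
#' @examples
#' s <- xyz_structure(c("C", "C", "O"),
#'                    rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.0, 1.2, 0)), -1)
#' kabsch_rmsd(s, s)  # 0
#' @export
kabsch_rmsd <- function(a, b, heavy_only = FALSE) {
  stopifnot(inherits(a, "xyz_structure"), inherits(b, "xyz_structure"))
  if (!identical(a$symbols, b$symbols))
    stop("atom symbol sequences differ; RMSD undefined without re-indexing")
  keep <- if (heavy_only) !(a$symbols %in% c("H", "D")) else
    rep(TRUE, length(a$symbols))
  X <- a$coords[keep, , drop = FALSE]
  Y <- b$coords[keep, , drop = FALSE]
  if (nrow(X) < 1L) stop("no atoms left to superpose")
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  if (nrow(X) == 1L) return(0)
  s <- svd(crossprod(Y, X))           # covariance t(Y) %*% X
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)           # proper rotation applied to X
  diffs <- X %*% t(R) - Y
  sqrt(sum(diffs^2) / nrow(X))
}

#' Rotational constants of a structure
#'
#' Principal rotational constants from the eigenvalues of the mass-weighted
#' inertia tensor about the center of mass, reported in MHz via
#' B = 505379.0 / I with I in amu Angstrom^2, sorted A >= B >= C. Linear
#' molecules (one vanishing moment) are flagged and return a single finite
#' constant with A set to `Inf`.
#'
#' @param structure An `xyz_structure` with at least 2 atoms.
#' @param linear_tol Relative tolerance on the smallest moment for declaring
#'   the molecule linear.
#' @return A list of class `rotational_constants` with fields `A`, `B`, `C`
#'   (MHz), `moments` (amu A^2, ascending) and `linear` (logical).
#' @examples
#' hh <- xyz_structure(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)), 0)
#' rotational_constants(hh)  # linear rotor, B = 505379 / (mu * d^2)
#' @export
rotational_constants <- function(structure, linear_tol = 1e-8) {
  stopifnot(inherits(structure, "xyz_structure"))
  n <- length(structure$symbols)
  if (n < 2L) stop("no rotational constants: structure has a single atom")
  m <- atomic_masses(structure$symbols)
  X <- structure$coords
  com <- colSums(X * m) / sum(m)
  X <- sweep(X, 2, com)
  xx <- X[, 1]; yy <- X[, 2]; zz <- X[, 3]
  I <- matrix(c(
    sum(m * (yy^2 + zz^2)), -sum(m * xx * yy),      -sum(m * xx * zz),
    -sum(m * xx * yy),      sum(m * (xx^2 + zz^2)), -sum(m * yy * zz),
    -sum(m * xx * zz),      -sum(m * yy * zz),      sum(m * (xx^2 + yy^2))),
    nrow = 3, byrow = TRUE)
  mom <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  mom[mom < 0] <- 0                    # numerical guard
  linear <- mom[1] < linear_tol * max(mom)
  consts <- ifelse(mom > 0, .const$rotconst_mhz / mom, Inf)
  # moments ascending => constants descending: A >= B >= C
  out <- list(A = consts[1], B = consts[2], C = consts[3],
              moments = mom, linear = linear)
  class(out) <- "rotational_constants"
  out
}

#' @export
print.rotational_constants <- function(x, ...) {
  if (x$linear) {
    cat(sprintf("<rotational_constants> linear rotor, B = %.4f MHz\n", x$B))
  } else {
    cat(sprintf("<rotational_constants> A=%.4f B=%.4f C=%.4f MHz\n",
                x$A, x$B, x$C))
  }
  invisible(x)
}

#' Relative difference between two sets of rotational constants
#'
#' The comparison used by the CRE classifier: the maximum over the principal
#' constants of |delta| / mean. Linear rotors compare their single finite
#' constant.
#'
#' @param ra,rb `rotational_constants` objects.
#' @return Non-negative scalar (unitless relative difference).
#' @export
rotconst_rel_diff <- function(ra, rb) {
  pick <- function(r) {
    v <- c(r$A, r$B, r$C)
    v[is.finite(v)]
  }
  va <- pick(ra); vb <- pick(rb)
  if (length(va) != length(vb))
    return(Inf)                        # linear vs nonlinear: always distinct
  max(abs(va - vb) / ((va + vb) / 2))
}
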