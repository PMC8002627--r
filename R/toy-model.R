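## Synthetic toy torsional molecule with analytic conformer energies: a
## bead chain with fixed bond lengths/angles whose energy depends only on
## its torsion angles (plus an optional ellipsoid host wall acting on the
## chain centroid). Serves as a fully seeded stand-in for a quantum-chemical
## sampling engine, with a brute-force grid oracle for validation.

#' Construct a toy torsional molecule model
#'
#' A bead chain of `n_torsions + 3` atoms with fixed bond length and angle.
#' The potential is a sum of per-torsion cosine series
#' `sum_k amplitude * (1 - cos(multiplicity * (phi - phase)))`, an optional
#' nearest-neighbor torsion coupling
#' `coupling * sum_j (1 - cos(phi_j - phi_{j+1}))`, and, when a host is
#' present, a polynomial ellipsoid wall
#' `wall_k * max(0, q - 1)^wall_exp` on the chain centroid, where `q` is
#' the ellipsoid quadratic form. The potential is bounded below and the
#' energy depends only on the torsions (and the centroid position relative
#' to the host).
#'
#' The default single-torsion potential is a 3-fold rotor with a 3 kcal/mol
#' barrier, the textbook magnitude for a substituted alkane torsion.
#'
#' @param n_torsions Number of torsional degrees of freedom (>= 1).
#' @param torsion_terms List of length `n_torsions`; element `j` is a
#'   data.frame with columns `amplitude` (kcal/mol), `multiplicity`
#'   (integer), `phase` (rad) for torsion `j`. A single data.frame is
#'   recycled to all torsions.
#' @param coupling Nearest-neighbor torsion coupling constant, kcal/mol.
#' @param bond_length Chain bond length, Angstrom.
#' @param bond_angle Chain bond angle, degrees.
#' @param masses Atomic masses of the beads, amu; recycled to
#'   `n_torsions + 3`.
#' @param symbols Element symbols of the beads (for bookkeeping only).
#' @param host `NULL`, or a list with `semiaxes` (length-3, Angstrom),
#'   `wall_k` (kcal/mol) and `wall_exp` (even integer exponent).
#' @param seed Seed stored with the model; all sampling on the model
#'   derives its randomness from it.
#' @return An object of class `toy_torsion_model`.
#' @examples
#' m <- toy_torsion_model(1, torsion_terms = data.frame(
#'   amplitude = 1, multiplicity = 2, phase = 0))
#' toy_energy(m, 0)       # 0 at the minimum
#' toy_energy(m, pi / 2)  # 2 at the barrier top
#' @export
toy_torsion_model <- function(n_torsions,
                              torsion_terms = data.frame(
                                amplitude = 1.5, multiplicity = 3, phase = 0),
                              coupling = 0,
                              bond_length = 1.53, bond_angle = 111,
                              masses = 12.011, symbols = "C",
                              host = NULL, seed = 1L) {
  stopifnot(n_torsions >= 1)
  if (is.data.frame(torsion_terms))
    torsion_terms <- rep(list(torsion_terms), n_torsions)
  if (length(torsion_terms) != n_torsions)
    stop("torsion_terms must have one entry per torsion")
  for (tt in torsion_terms)
    stopifnot(all(c("amplitude", "multiplicity", "phase") %in% names(tt)))
  n_atoms <- n_torsions + 3L
  masses <- rep_len(masses, n_atoms)
  symbols <- rep_len(symbols, n_atoms)
  if (!is.null(host)) {
    stopifnot(length(host$semiaxes) == 3, all(host$semiaxes > 0),
              host$wall_k > 0, host$wall_exp >= 1)
  }
  structure(
    list(n_torsions = as.integer(n_torsions), torsion_terms = torsion_terms,
         coupling = coupling, bond_length = bond_length,
         bond_angle = bond_angle * pi / 180, masses = masses,
         symbols = symbols, host = host, seed = as.integer(seed)),
    class = "toy_torsion_model")
}

#' @export
print.toy_torsion_model <- function(x, ...) {
  cat(sprintf(
    "<toy_torsion_model> %d torsions, %d beads, coupling %.2f kcal/mol%s, seed %d\n",
    x$n_torsions, x$n_torsions + 3L, x$coupling,
    if (is.null(x$host)) "" else
      sprintf(", ellipsoid host (%.1f,%.1f,%.1f) A",
              x$host$semiaxes[1], x$host$semiaxes[2], x$host$semiaxes[3]),
    x$seed))
  invisible(x)
}

#' Toy-model potential energy
#'
#' @param model A [toy_torsion_model].
#' @param torsions Numeric vector of torsion angles, rad (length
#'   `n_torsions`).
#' @param position Centroid translation, Angstrom (length 3); only enters
#'   through the host wall term.
#' @return Energy in kcal/mol.
#' @export
toy_energy <- function(model, torsions, position = c(0, 0, 0)) {
  stopifnot(inherits(model, "toy_torsion_model"))
  if (length(torsions) != model$n_torsions)
    stop("expected ", model$n_torsions, " torsions, got ", length(torsions))
  e <- 0
  for (j in seq_len(model$n_torsions)) {
    tt <- model$torsion_terms[[j]]
    e <- e + sum(tt$amplitude *
                   (1 - cos(tt$multiplicity * (torsions[j] - tt$phase))))
  }
  if (model$coupling != 0 && model$n_torsions > 1) {
    dphi <- diff(torsions)
    e <- e + model$coupling * sum(1 - cos(dphi))
  }
  if (!is.null(model$host)) {
    cen <- colMeans(embed_torsions(model, torsions, energy = 0)$coords) +
      position
    q <- sum((cen / model$host$semiaxes)^2)
    if (q > 1) e <- e + model$host$wall_k * (q - 1)^model$host$wall_exp
  }
  e
}

## NeRF placement of atom D given A,B,C and internal coordinates
.place_atom <- function(A, B, C, bond, angle, dihedral) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(dihedral),
          -bond * sin(angle) * sin(dihedral))
  C + cbind(bc, m, n) %*% d2
}

#' Build Cartesian coordinates of the toy chain at given torsions
#'
#' Standard internal-to-Cartesian construction with fixed bond lengths and
#' angles; deterministic canonical placement (first atom at the origin,
#' second along x, third in the xy plane).
#'
#' @param model A [toy_torsion_model].
#' @param torsions Torsion angles, rad.
#' @param energy Optional energy to store on the structure; computed from
#'   `toy_energy` when `NULL`.
#' @param position Centroid translation applied to the final coordinates.
#' @return An [xyz_structure] with a `torsions` attribute.
#' @export
embed_torsions <- function(model, torsions, energy = NULL,
                           position = c(0, 0, 0)) {
  stopifnot(inherits(model, "toy_torsion_model"),
            length(torsions) == model$n_torsions)
  b <- model$bond_length; th <- model$bond_angle
  n <- model$n_torsions + 3L
  X <- matrix(0, n, 3)
  X[2, ] <- c(b, 0, 0)
  X[3, ] <- X[2, ] + c(-b * cos(th), b * sin(th), 0)
  for (i in 4:n) {
    X[i, ] <- .place_atom(X[i - 3, ], X[i - 2, ], X[i - 1, ],
                          b, th, torsions[i - 3])
  }
  X <- sweep(X, 2, -position)
  if (is.null(energy)) {
    s <- xyz_structure(model$symbols, X, 0)
    s$energy <- toy_energy(model, torsions, position)
  } else {
    s <- xyz_structure(model$symbols, X, energy)
  }
  attr(s, "torsions") <- as.numeric(torsions)
  s
}

#' Measure the chain torsion angles of a structure
#'
#' Dihedral angles over consecutive atom quadruples, in (-pi, pi].
#'
#' @param structure An [xyz_structure] built on the toy chain topology.
#' @return Numeric vector of torsions, rad.
#' @export
measure_torsions <- function(structure) {
  X <- structure$coords
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 atoms for a torsion")
  vapply(seq_len(n - 3L), function(i) {
    b1 <- X[i + 1, ] - X[i, ]
    b2 <- X[i + 2, ] - X[i + 1, ]
    b3 <- X[i + 3, ] - X[i + 2, ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
            b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
            b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
            n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
    atan2(sum(m1 * n2), sum(n1 * n2))
  }, numeric(1))
}

.wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y <= -pi, y + 2 * pi, y)
}

#' Brute-force grid reference for a toy model
#'
#' Exhaustively evaluates the torsional potential on a regular periodic
#' grid, locates local minima, assigns every grid point to a basin by
#' steepest descent over grid neighbors, and computes basin populations
#' from the grid partition sum at temperature `T`. This is the oracle
#' against which stochastic sampling is validated.
#'
#' @param model A [toy_torsion_model] (host wall ignored: the oracle
#'   characterizes the free torsional surface).
#' @param grid_points Grid points per torsion (>= 36).
#' @param T Temperature for the populations, K.
#' @return A list with `minima` (matrix, one torsion vector per row, energy
#'   ascending), `energies` (kcal/mol at the minima), `populations` (basin
#'   Boltzmann populations, same order), and `grid_points`.
#' @examples
#' m <- toy_torsion_model(1, data.frame(amplitude = 1, multiplicity = 2,
#'                                      phase = 0))
#' brute_force_reference(m, 72)  # two minima at 0 and pi, populations 1/2
#' @export
brute_force_reference <- function(model, grid_points = 36, T = 298.15) {
  stopifnot(inherits(model, "toy_torsion_model"))
  if (grid_points < 36) stop("grid must have at least 36 points per torsion")
  n <- model$n_torsions
  if (grid_points^n > 1e7) stop("grid too large: ", grid_points, "^", n)
  phi <- seq(0, 2 * pi, length.out = grid_points + 1)[seq_len(grid_points)]
  grids <- do.call(expand.grid, rep(list(phi), n))
  npts <- nrow(grids)
  # strip host so the oracle reflects the intrinsic torsional surface
  free_model <- model
  free_model$host <- NULL
  E <- vapply(seq_len(npts), function(i)
    toy_energy(free_model, as.numeric(grids[i, ])), numeric(1))
  # index arithmetic on the periodic n-dim grid
  idx <- as.matrix(do.call(expand.grid,
                           rep(list(seq_len(grid_points)), n)))
  # Moore neighborhood offsets
  offs <- as.matrix(do.call(expand.grid, rep(list(c(-1L, 0L, 1L)), n)))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  strides <- grid_points^(seq_len(n) - 1L)
  to_lin <- function(ix) as.integer((ix - 1L) %*% strides + 1L)
  # steepest-descent pointer for every grid point
  pointer <- integer(npts)
  for (i in seq_len(npts)) {
    nb_ix <- sweep(offs, 2, idx[i, ], `+`)
    nb_ix <- ((nb_ix - 1L) %% grid_points) + 1L
    nb <- to_lin(nb_ix)
    j <- nb[which.min(E[nb])]
    pointer[i] <- if (E[j] < E[i]) j else i
  }
  # pointer jumping until every chain terminates at a local minimum
  repeat {
    nxt <- pointer[pointer]
    if (identical(nxt, pointer)) break
    pointer <- nxt
  }
  mins <- sort(unique(pointer))
  w <- exp(-(E - min(E)) / (.const$R_kcal * T))
  pop <- vapply(mins, function(mi) sum(w[pointer == mi]), numeric(1)) / sum(w)
  ord <- order(E[mins])
  list(minima = as.matrix(grids)[mins[ord], , drop = FALSE],
       energies = E[mins[ord]],
       populations = pop[ord],
       grid_points = grid_points)
}

#' Locally optimize torsion vectors to their basin minima
#'
#' Quenches sampled snapshots: each torsion vector is relaxed to its local
#' minimum of the (host-free) torsional potential with BFGS, mirroring the
#' snapshot geometry optimization that precedes CRE assembly in conformer
#' search workflows.
#'
#' @param model A [toy_torsion_model].
#' @param torsion_matrix Matrix with one torsion vector per row, or a
#'   [conformer_ensemble] carrying a `torsions` attribute.
#' @return A [conformer_ensemble] of quenched structures (with `torsions`
#'   attributes and minimized energies), in input order.
#' @export
quench_ensemble <- function(model, torsion_matrix) {
  stopifnot(inherits(model, "toy_torsion_model"))
  if (inherits(torsion_matrix, "conformer_ensemble")) {
    torsion_matrix <- attr(torsion_matrix, "torsions")
    if (is.null(torsion_matrix))
      stop("ensemble carries no torsions attribute")
  }
  torsion_matrix <- as.matrix(torsion_matrix)
  free_model <- model
  free_model$host <- NULL                 # wall removed for optimization
  f <- function(phi) toy_energy(free_model, phi)
  structs <- lapply(seq_len(nrow(torsion_matrix)), function(i) {
    res <- stats::optim(torsion_matrix[i, ], f, method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 500))
    embed_torsions(free_model, .wrap_angle(res$par), energy = res$value)
  })
  ens <- conformer_ensemble(structs, provenance = "quench_ensemble")
  attr(ens, "torsions") <- t(vapply(structs, attr, numeric(model$n_torsions),
                                    "torsions"))
  ens
}

#' Numerical torsional vibrational frequencies at a minimum
#'
#' Central-finite-difference Hessian of the torsional potential,
#' mass-weighted by the per-torsion effective moments of inertia
#' `I_j = sum_a m_a |dr_a/dphi_j|^2` (computed from the chain embedding
#' with the leading three atoms held fixed), diagonalized to harmonic
#' frequencies in cm^-1. The input must be a local minimum: a large
#' gradient or negative curvature raises an error naming the imaginary
#' modes.
#'
#' @param model A [toy_torsion_model].
#' @param torsions Torsion vector at a local minimum, rad.
#' @param step Finite-difference step, rad.
#' @param grad_tol Gradient-norm tolerance (kcal/mol/rad) for accepting the
#'   point as a minimum.
#' @return Numeric vector of harmonic frequencies, cm^-1, ascending.
#' @export
numerical_frequencies <- function(model, torsions, step = 1e-3,
                                  grad_tol = 1e-4) {
  stopifnot(inherits(model, "toy_torsion_model"),
            length(torsions) == model$n_torsions)
  free_model <- model
  free_model$host <- NULL
  f <- function(phi) toy_energy(free_model, phi)
  n <- model$n_torsions
  grad <- vapply(seq_len(n), function(j) {
    e <- rep(0, n); e[j] <- step
    (f(torsions + e) - f(torsions - e)) / (2 * step)
  }, numeric(1))
  if (sqrt(sum(grad^2)) > grad_tol)
    stop("input is not a stationary point (|grad| = ",
         format(sqrt(sum(grad^2))), " kcal/mol/rad)")
  H <- matrix(0, n, n)
  f0 <- f(torsions)
  for (j in seq_len(n)) {
    ej <- rep(0, n); ej[j] <- step
    H[j, j] <- (f(torsions + ej) - 2 * f0 + f(torsions - ej)) / step^2
    if (j < n) for (l in (j + 1):n) {
      el <- rep(0, n); el[l] <- step
      H[j, l] <- H[l, j] <-
        (f(torsions + ej + el) - f(torsions + ej - el) -
           f(torsions - ej + el) + f(torsions - ej - el)) / (4 * step^2)
    }
  }
  I <- torsion_inertia(model, torsions)
  W <- diag(1 / sqrt(I), n)
  lam <- eigen(W %*% H %*% W, symmetric = TRUE, only.values = TRUE)$values
  # lam in (kcal/mol)/(amu A^2); omega^2 [s^-2] = lam * cal_J*1e3/(amu_kg*NA*1e-20)
  k <- .const
  conv <- k$cal_J * 1e3 / (k$amu_kg * k$NA_SI * 1e-20)
  neg <- lam < -1e-8 * max(abs(lam))
  if (any(neg)) {
    nu_im <- sqrt(-lam[neg] * conv) / (2 * pi * k$c_cm)
    stop("imaginary mode(s) at a non-minimum: ",
         paste(sprintf("%.1fi cm^-1", nu_im), collapse = ", "))
  }
  lam[lam < 0] <- 0
  sort(sqrt(lam * conv) / (2 * pi * k$c_cm))
}

#' Effective torsional moments of inertia
#'
#' `I_j = sum_a m_a |dr_a/dphi_j|^2` by finite differences of the chain
#' embedding (leading three atoms fixed), amu Angstrom^2.
#'
#' @param model A [toy_torsion_model].
#' @param torsions Torsion vector, rad.
#' @param step Finite-difference step, rad.
#' @return Numeric vector, one moment per torsion.
#' @export
torsion_inertia <- function(model, torsions, step = 1e-4) {
  n <- model$n_torsions
  vapply(seq_len(n), function(j) {
    e <- rep(0, n); e[j] <- step
    Xp <- embed_torsions(model, torsions + e)$coords
    Xm <- embed_torsions(model, torsions - e)$coords
    dX <- (Xp - Xm) / (2 * step)
    sum(model$masses * rowSums(dX^2))
  }, numeric(1))
}
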