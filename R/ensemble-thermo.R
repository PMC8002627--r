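## RRHO thermochemistry and Boltzmann ensemble statistics: per-structure
## Gibbs corrections, weights, average and partition-sum free energies,
## conformational entropy S_CR and its free-energy contribution G_CR.

#' Rigid-rotor harmonic-oscillator thermochemistry
#'
#' Standard ideal-gas RRHO corrections for one structure: translational
#' entropy from the Sackur-Tetrode equation, rotational entropy from the
#' linear/nonlinear rigid-rotor closed forms, harmonic-oscillator
#' vibrational sums, zero-point energy, thermal enthalpy (including the RT
#' pV term), and the full Gibbs correction
#' `g_rrho = zpe + h_corr - T * (s_trans + s_rot + s_vib)`.
#'
#' @param frequencies_cm1 Vibrational frequencies in cm^-1 (all >= 0;
#'   imaginary modes must be removed beforehand or an error names them).
#'   May be empty (an atom).
#' @param masses_amu Atomic masses, amu (only the total mass enters).
#' @param rot_constants A [rotational_constants] object, or `NULL` for a
#'   single atom (no rotational contribution).
#' @param T Temperature, K (> 0).
#' @param symmetry_number Rotational symmetry number (default 1).
#' @param pressure Pressure in atm (default 1).
#' @param freq_scale Harmonic frequency scaling factor (default 1.0).
#' @return A list of class `thermo_result` with `zpe`, `h_corr` (kcal/mol),
#'   `s_trans`, `s_rot`, `s_vib` (kcal/(mol K)), and `g_rrho` (kcal/mol).
#' @examples
#' # one 1000 cm^-1 mode: zpe ~ 1.4296 kcal/mol
#' rrho_thermo(1000, masses_amu = c(12.011, 12.011),
#'             rot_constants = NULL, T = 298.15)$zpe
#' @export
rrho_thermo <- function(frequencies_cm1, masses_amu, rot_constants = NULL,
                        T = 298.15, symmetry_number = 1, pressure = 1,
                        freq_scale = 1.0) {
  if (T <= 0) stop("temperature must be positive")
  frequencies_cm1 <- as.numeric(frequencies_cm1) * freq_scale
  if (any(frequencies_cm1 < 0))
    stop("negative (imaginary) frequencies at mode index ",
         paste(which(frequencies_cm1 < 0), collapse = ", "),
         "; remove or re-optimize first")
  k <- .const
  R <- k$R_kcal
  # translation: Sackur-Tetrode
  m_kg <- sum(masses_amu) * k$amu_kg
  p_Pa <- pressure * 101325
  kT <- k$kB_SI * T
  q_trans <- (2 * pi * m_kg * kT / k$h_SI^2)^1.5 * (kT / p_Pa)
  s_trans <- R * (log(q_trans) + 2.5)
  h_trans <- 2.5 * R * T                       # 3/2 RT + RT (pV)
  # rotation
  if (is.null(rot_constants)) {
    s_rot <- 0; h_rot <- 0
  } else {
    stopifnot(inherits(rot_constants, "rotational_constants"))
    theta <- function(B_MHz) k$h_SI * B_MHz * 1e6 / k$kB_SI  # K
    if (rot_constants$linear) {
      th <- theta(rot_constants$B)
      s_rot <- R * (log(T / (symmetry_number * th)) + 1)
      h_rot <- R * T
    } else {
      thABC <- theta(c(rot_constants$A, rot_constants$B, rot_constants$C))
      q_rot <- sqrt(pi) / symmetry_number * sqrt(T^3 / prod(thABC))
      s_rot <- R * (log(q_rot) + 1.5)
      h_rot <- 1.5 * R * T
    }
  }
  # vibration: harmonic oscillator, frequencies in temperature units
  nu <- frequencies_cm1[frequencies_cm1 > 0]
  zpe <- 0.5 * sum(frequencies_cm1) * k$cm1_kcal
  if (length(nu)) {
    x <- k$h_SI * k$c_cm * nu / (k$kB_SI * T)
    s_vib <- R * sum(x / expm1(x) - log1p(-exp(-x)))
    h_vib <- R * T * sum(x / expm1(x))
  } else {
    s_vib <- 0; h_vib <- 0
  }
  h_corr <- h_trans + h_rot + h_vib
  s_tot <- s_trans + s_rot + s_vib
  out <- list(zpe = zpe, h_corr = h_corr, s_trans = s_trans, s_rot = s_rot,
              s_vib = s_vib, g_rrho = zpe + h_corr - T * s_tot,
              temperature = T)
  class(out) <- "thermo_result"
  out
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    "<thermo_result> T=%.2f K: ZPE=%.4f, Hcorr=%.4f kcal/mol, S(t/r/v)=%.5f/%.5f/%.5f, Grrho=%.4f\n",
    x$temperature, x$zpe, x$h_corr, x$s_trans, x$s_rot, x$s_vib, x$g_rrho))
  invisible(x)
}

#' Gibbs free energy of one structure
#'
#' `G = E_total + g_rrho + g_solv`, with absent terms treated as zero. When
#' the thermochemical correction is missing a warning is raised (the value
#' is then `E + g_solv`).
#'
#' @param energy_total Electronic total energy, kcal/mol.
#' @param g_rrho RRHO Gibbs correction, kcal/mol, or `NA`.
#' @param g_solv Solvation free energy, kcal/mol, or `NA`.
#' @param warn_missing Warn when `g_rrho` is absent.
#' @return Gibbs free energy, kcal/mol.
#' @examples
#' gibbs_energy(-10, 2, -1)  # -9
#' @export
gibbs_energy <- function(energy_total, g_rrho = NA_real_, g_solv = NA_real_,
                         warn_missing = TRUE) {
  stopifnot(is.finite(energy_total))
  if (is.na(g_rrho)) {
    if (warn_missing)
      warning("no thermochemical correction supplied; G = E + g_solv")
    g_rrho <- 0
  }
  if (is.na(g_solv)) g_solv <- 0
  energy_total + g_rrho + g_solv
}

#' Boltzmann weights of a set of free energies
#'
#' `p_i` proportional to `exp(-(G_i - G_min) / RT)`, normalized to one.
#' Shift-invariant by construction (the minimum is subtracted first).
#'
#' @param G Numeric vector of free energies, kcal/mol (non-empty).
#' @param T Temperature, K (> 0).
#' @return Numeric vector of weights summing to 1.
#' @examples
#' boltzmann_weights(c(0, 0), 298.15)            # 0.5 0.5
#' RT <- phys_constants()$R_kcal * 298.15
#' boltzmann_weights(c(0, RT * log(2)), 298.15)  # 2/3 1/3
#' @export
boltzmann_weights <- function(G, T = 298.15) {
  if (length(G) == 0L) stop("empty free-energy list")
  if (T <= 0) stop("temperature must be positive")
  w <- exp(-(G - min(G)) / (.const$R_kcal * T))
  w / sum(w)
}

#' Boltzmann summary of an ensemble of free energies
#'
#' Computes the ensemble statistics for a list of per-structure free
#' energies: weights `p_i`, the weighted average `<G> = sum p_i G_i`, the
#' partition-sum free energy `F = -RT log sum exp(-G_i/RT)`, the
#' conformational-rotational entropy `S_CR = -R sum p_i log p_i` (natural
#' logarithm), and its free-energy contribution `G_CR = -T * S_CR`. The
#' identity `F = <G> - T * S_CR` holds exactly.
#'
#' @param G Numeric vector of free energies, kcal/mol (non-empty).
#' @param T Temperature, K (> 0).
#' @return A list of class `boltzmann_summary` with `weights`, `g_avg`,
#'   `f_ens` (kcal/mol), `s_cr` (kcal/(mol K)), `g_cr` (kcal/mol),
#'   `temperature`, `n`.
#' @examples
#' bs <- ensemble_summary(rep(0, 4), 298.15)
#' bs$s_cr  # R * log(4)
#' bs$g_cr  # about -0.8214 kcal/mol
#' @export
ensemble_summary <- function(G, T = 298.15) {
  p <- boltzmann_weights(G, T)
  R <- .const$R_kcal
  g_avg <- sum(p * G)
  f_ens <- min(G) - R * T * log(sum(exp(-(G - min(G)) / (R * T))))
  plogp <- ifelse(p > 0, p * log(p), 0)
  s_cr <- -R * sum(plogp)
  out <- list(weights = p, g_avg = g_avg, f_ens = f_ens, s_cr = s_cr,
              g_cr = -T * s_cr, temperature = T, n = length(G))
  class(out) <- "boltzmann_summary"
  out
}

#' @export
print.boltzmann_summary <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_summary> n=%d, T=%.2f K: <G>=%.4f, F=%.4f kcal/mol, S_CR=%.6f kcal/(mol K), G_CR=%.4f\n",
    x$n, x$temperature, x$g_avg, x$f_ens, x$s_cr, x$g_cr))
  cat("  top weights:",
      paste(sprintf("%.4f", utils::head(sort(x$weights, decreasing = TRUE), 5)),
            collapse = " "), "\n")
  invisible(x)
}
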