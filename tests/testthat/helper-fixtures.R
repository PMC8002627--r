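# Shared generators for random structures, rigid motions and ensembles.

random_structure <- function(n = 8, symbols = NULL, energy = NULL,
                             spread = 2) {
  if (is.null(symbols)) symbols <- sample(c("C", "N", "O", "H"), n, TRUE)
  if (is.null(energy)) energy <- stats::rnorm(1)
  xyz_structure(symbols, matrix(stats::rnorm(3 * n, sd = spread), n, 3),
                energy)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigid_move <- function(s, R = random_rotation(),
                       t = stats::rnorm(3, sd = 5)) {
  xyz_structure(s$symbols, sweep(s$coords %*% t(R), 2, -t), s$energy,
                g_rrho = s$g_rrho, g_solv = s$g_solv, tag = s$tag)
}

random_ensemble <- function(n_frames = 4, n_atoms = 6) {
  symbols <- sample(c("C", "N", "O"), n_atoms, TRUE)
  conformer_ensemble(lapply(seq_len(n_frames), function(i)
    random_structure(n_atoms, symbols = symbols)))
}

# Independent superposition oracle: minimal RMSD over a ZYZ Euler-angle
# rotation grid after centroid alignment; coarse pass then 1-degree
# refinement around the best candidates. Never calls kabsch_rmsd().
grid_rmsd <- function(a, b, coarse = 10, top = 3) {
  X <- sweep(a$coords, 2, colMeans(a$coords))
  Y <- sweep(b$coords, 2, colMeans(b$coords))
  n <- nrow(X)
  eval_grid <- function(al, be, ga) {
    g <- expand.grid(al = al, be = be, ga = ga)
    ca <- cos(g$al); sa <- sin(g$al)
    cb <- cos(g$be); sb <- sin(g$be)
    cc <- cos(g$ga); sc <- sin(g$ga)
    # R = Rz(al) Ry(be) Rz(ga), columns stacked per rotation
    K <- nrow(g)
    R <- rbind(
      c(rbind(ca * cb * cc - sa * sc, sa * cb * cc + ca * sc, -sb * cc)),
      c(rbind(-ca * cb * sc - sa * cc, -sa * cb * sc + ca * cc, sb * sc)),
      c(rbind(ca * sb, sa * sb, cb)))
    XR <- X %*% matrix(R, nrow = 3)          # n x 3K
    D2 <- (XR - matrix(Y, n, 3 * K))^2
    ss <- colSums(D2)
    rss <- ss[seq(1, 3 * K, 3)] + ss[seq(2, 3 * K, 3)] + ss[seq(3, 3 * K, 3)]
    list(rss = rss, g = g)
  }
  d2r <- pi / 180
  cg <- eval_grid(seq(0, 350, coarse) * d2r,
                  seq(0, 180, coarse) * d2r,
                  seq(0, 350, coarse) * d2r)
  best <- order(cg$rss)[seq_len(top)]
  best_rss <- min(cg$rss)
  for (i in best) {
    g0 <- cg$g[i, ]
    fine <- eval_grid(g0$al + seq(-coarse, coarse, 1) * d2r,
                      g0$be + seq(-coarse, coarse, 1) * d2r,
                      g0$ga + seq(-coarse, coarse, 1) * d2r)
    # polish at 0.2 degrees around the 1-degree optimum
    g1 <- fine$g[which.min(fine$rss), ]
    fine2 <- eval_grid(g1$al + seq(-1, 1, 0.2) * d2r,
                       g1$be + seq(-1, 1, 0.2) * d2r,
                       g1$ga + seq(-1, 1, 0.2) * d2r)
    best_rss <- min(best_rss, fine$rss, fine2$rss)
  }
  sqrt(best_rss / n)
}

table2_path <- function() {
  system.file("extdata", "table2_reference.csv", package = "crebind")
}
table4_path <- function() {
  system.file("extdata", "table4_association.csv", package = "crebind")
}
g0_path <- function() {
  system.file("extdata", "g0_protonation.csv", package = "crebind")
}

# Asymmetric 2-torsion model shared by the sampling-validation tests:
# double wells on each torsion, with the first torsion's two minima split
# by ~0.4 kcal/mol, giving four conformers with unequal populations.
recovery_model <- function() {
  toy_torsion_model(
    2,
    torsion_terms = list(
      rbind(data.frame(amplitude = 1.2, multiplicity = 2, phase = 0),
            data.frame(amplitude = -0.2, multiplicity = 1, phase = 0)),
      data.frame(amplitude = 1.2, multiplicity = 2, phase = 0)),
    seed = 42)
}
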