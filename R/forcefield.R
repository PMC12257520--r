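# R surface over the compiled q-TIP4P/F evaluator.

ff_to_cpp <- function(ff) {
  list(D_r = ff$D_r, alpha_r = ff$alpha_r, r_eq = ff$r_eq,
       k_theta = ff$k_theta, theta_eq = ff$theta_eq,
       epsilon = ff$epsilon, sigma = ff$sigma,
       q_H = ff$q_H, q_M = ff$q_M, m_site_weight = ff$m_site_weight,
       r_c = ff$r_c, eps_rf = ff$eps_rf, shift_rf = ff$shift_rf)
}

check_config <- function(positions) {
  d <- dim(positions)
  if (is.null(d) || length(d) != 4 || d[1] != 3 || d[2] != 3)
    stop("positions must be an array 3 x 3 x n_molecules x n_beads")
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  d
}

#' q-TIP4P/F potential energy and forces
#'
#' Evaluates the full potential (intramolecular quartic-Morse stretches and
#' harmonic bend, plus intermolecular Lennard-Jones and reaction-field
#' Coulomb) for a bead configuration. Each bead slice interacts only with
#' the same bead index of other molecules (standard discretized
#' path-integral factorization). Forces on the massless M site are
#' redistributed to the three massive sites by the transpose of the
#' placement weights.
#'
#' @param positions Array 3 x 3 x n_molecules x n_beads (nm); site order
#'   O, X1, X2.
#' @param L Box edge (nm) for periodic boundaries; `L <= 0` for an
#'   isolated system.
#' @param ff Force-field constants (`qtip4pf_constants()`).
#' @param intra,inter Include the intra-/intermolecular terms.
#' @return List with `energy` (kJ/mol per bead slice), `forces`
#'   (same shape as `positions`) and `virial` (per bead slice).
#' @export
total_potential <- function(positions, L = -1, ff = qtip4pf_constants(),
                            intra = TRUE, inter = TRUE) {
  d <- check_config(positions)
  if (L > 0 && d[3] > 1 && L < 2 * ff$r_c)
    stop("cell edge must be >= 2 r_c; reduce the cutoff for small boxes")
  qtip4pf_eval_cpp(positions, d[3], d[4], L, ff_to_cpp(ff),
                   intra = intra, inter = inter)
}

#' @rdname total_potential
#' @export
intramolecular_energy_forces <- function(positions, L = -1,
                                         ff = qtip4pf_constants()) {
  d <- check_config(positions)
  qtip4pf_eval_cpp(positions, d[3], d[4], L, ff_to_cpp(ff),
                   intra = TRUE, inter = FALSE)
}

#' @rdname total_potential
#' @export
intermolecular_energy_forces <- function(positions, L = -1,
                                         ff = qtip4pf_constants()) {
  d <- check_config(positions)
  if (L > 0 && d[3] > 1 && L < 2 * ff$r_c)
    stop("cell edge must be >= 2 r_c; reduce the cutoff for small boxes")
  qtip4pf_eval_cpp(positions, d[3], d[4], L, ff_to_cpp(ff),
                   intra = FALSE, inter = TRUE)
}

#' M-site geometry
#'
#' Positions of the massless charged M site for every molecule and bead:
#' a fixed linear combination of the O, X1, X2 positions,
#' `M = gamma O + (1 - gamma)/2 (X1 + X2)`, which places M on the HOH
#' bisector. The returned redistribution weights are the coefficients by
#' which a force acting on M is transferred to the massive sites.
#'
#' @inheritParams total_potential
#' @return List with `m_positions` (array 3 x n_molecules x n_beads) and
#'   `weights` (named vector O/X1/X2).
#' @export
m_site_geometry <- function(positions, L = -1, ff = qtip4pf_constants()) {
  d <- check_config(positions)
  g <- ff$m_site_weight
  mp <- m_site_positions_cpp(positions, d[3], d[4], L, g)
  list(m_positions = mp,
       weights = c(O = g, X1 = (1 - g) / 2, X2 = (1 - g) / 2))
}

#' Harmonic normal modes of an isolated monomer
#'
#' Mass-weighted normal-mode analysis of one molecule at its potential
#' minimum, from a central-finite-difference Hessian of the intramolecular
#' potential. Used to check isotope frequency shifts: in the harmonic
#' small-amplitude limit the stretch frequency scales as the inverse square
#' root of the OX reduced mass.
#'
#' @param system An `isotope_system` (n_molecules is ignored; one molecule
#'   is analysed).
#' @param ff Force-field constants.
#' @param h Finite-difference step (nm).
#' @return List with `frequencies_cm` (vibrational frequencies, cm^-1,
#'   increasing; zero/translation/rotation modes removed) and `all_cm`.
#' @export
monomer_normal_modes <- function(system, ff = qtip4pf_constants(), h = 1e-5) {
  geo <- monomer_geometry(ff)
  x0 <- array(geo, dim = c(3, 3, 1, 1))
  n <- 9
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    fp <- as.numeric(intramolecular_energy_forces(xp, ff = ff)$forces)
    fm <- as.numeric(intramolecular_energy_forces(xm, ff = ff)$forces)
    H[, i] <- -(fp - fm) / (2 * h)   # Hessian column = -dF/dx
  }
  H <- (H + t(H)) / 2
  m3 <- rep(system$site_masses, each = 3)
  Hmw <- H / sqrt(outer(m3, m3))
  ev <- eigen(Hmw, symmetric = TRUE)$values
  ev[ev < 0 & ev > -1e-6] <- 0
  omega <- sqrt(pmax(ev, 0))                # rad/ps
  freq_cm <- sort(omega) / (2 * pi) / .c_cm_per_ps
  list(frequencies_cm = tail(freq_cm, 3), all_cm = freq_cm)
}
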