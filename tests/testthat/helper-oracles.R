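# Independent oracles, kept deliberately separate from the implementation
# paths they check.

.pc <- physical_constants()

# Central finite-difference gradient of a scalar energy function.
fd_forces <- function(positions, efun, h = 1e-5) {
  g <- array(0, dim = dim(positions))
  for (i in seq_along(positions)) {
    xp <- positions; xp[i] <- xp[i] + h
    xm <- positions; xm[i] <- xm[i] - h
    g[i] <- -(efun(xp) - efun(xm)) / (2 * h)
  }
  g
}

# Cyclic bead-coupling matrix of sum_k (x_{k+1} - x_k)^2, assembled
# edge by edge (the 2-bead ring has a doubled edge).
ring_coupling_matrix <- function(n_b) {
  K <- matrix(0, n_b, n_b)
  for (i in seq_len(n_b)) {
    j <- i %% n_b + 1
    K[i, i] <- K[i, i] + 1
    K[j, j] <- K[j, j] + 1
    K[i, j] <- K[i, j] - 1
    K[j, i] <- K[j, i] - 1
  }
  K
}

# Free ring-polymer <R_g^2> by brute-force normal-mode summation:
# sum over internal modes of the per-mode Gaussian variance
# n_b / (beta m omega_k^2), with omega_k from direct diagonalization of
# the bead-coupling (cyclic spring) matrix.
rg2_brute_force <- function(T, m, n_b, dims = 3) {
  if (n_b == 1) return(0)
  beta <- 1 / (.pc$kB * T)
  wn <- n_b / (beta * .pc$hbar)
  K <- ring_coupling_matrix(n_b)
  lam <- sort(eigen(m * wn^2 * K, symmetric = TRUE)$values) # m omega_k^2
  lam <- lam[-1]                                            # drop centroid
  dims * sum(n_b / (beta * lam)) / n_b
}

# Exact <E> of a 1-D harmonic oscillator discretized with n_b beads:
# numerical derivative of the exact log partition function (Gaussian
# normal-mode integrals), times `dims` dimensions.
ho_energy_exact <- function(T, m, omega, n_b, dims = 3) {
  beta <- 1 / (.pc$kB * T)
  lnZ <- function(b) {
    wn <- n_b / (b * .pc$hbar)
    wk <- 2 * wn * sin(pi * (0:(n_b - 1)) / n_b)
    bn <- b / n_b
    sum(-0.5 * log(wk^2 + omega^2)) - 0.5 * n_b * log(bn) +
      0.5 * n_b * log(2 * pi / bn)
  }
  h <- beta * 1e-6
  dims * (-(lnZ(beta + h) - lnZ(beta - h)) / (2 * h))
}

# Quantum-limit harmonic oscillator energy (per dimension times dims).
ho_energy_quantum <- function(T, omega, dims = 3) {
  beta <- 1 / (.pc$kB * T)
  x <- .pc$hbar * omega
  dims * (x / 2) / tanh(beta * x / 2)
}

# Plain O(N^2) hydrogen-bond detector, written independently in R.
hb_brute_force <- function(coords, L, d_max = 0.35, theta_max = 30) {
  nmol <- dim(coords)[3]
  mi <- function(v) if (L > 0) v - L * round(v / L) else v
  bonds <- 0
  found <- list()
  for (don in seq_len(nmol)) for (acc in seq_len(nmol)) {
    if (don == acc) next
    doo <- mi(coords[, 1, acc] - coords[, 1, don])
    r <- sqrt(sum(doo^2))
    if (r >= d_max) next
    for (s in 2:3) {
      xv <- mi(coords[, s, don] - coords[, 1, don])
      ang <- acos(min(1, max(-1, sum(xv * doo) /
                               (sqrt(sum(xv^2)) * r)))) * 180 / pi
      if (ang < theta_max) {
        bonds <- bonds + 1
        found[[bonds]] <- c(don, s - 1, acc)
      }
    }
  }
  list(n = bonds, bonds = found)
}

# Hand-evaluated shifted reaction-field pair energy for two unit point
# charges (used against the compiled Coulomb kernel).
rf_pair_energy <- function(r, q1, q2, r_c, eps_rf, shift = TRUE) {
  krf <- (eps_rf - 1) / ((2 * eps_rf + 1) * r_c^3)
  crf <- if (shift) 1 / r_c + krf * r_c^2 else 0
  if (r >= r_c) return(0)
  .pc$ke_coul * q1 * q2 * (1 / r + krf * r^2 - crf)
}

# Reduced-mass harmonic stretch ratio oracle.
stretch_ratio_oracle <- function(mH = 1.00783, mD = 2.01410, mO = 15.9949) {
  muOH <- mO * mH / (mO + mH)
  muOD <- mO * mD / (mO + mD)
  sqrt(muOD / muOH)
}
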