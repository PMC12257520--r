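# Seed-deterministic synthetic fixtures with known statistics: free ring
# polymers, tetrahedral lattices, hydrogen-bonded dimers, spectral toys
# and observable curve families. Each generator records its spec so that
# any output is regenerable.

#' Exact free-ring-polymer sampler
#'
#' Samples bead configurations of a free ring polymer from the exact
#' normal-mode Gaussian distribution: mode k has variance
#' `n_b / (beta m omega_k^2)` per dimension (centroid pinned at the
#' origin). The sampled 3-D gyration radius has closed-form mean
#' `<R_g^2> = beta hbar^2 / (4 m) (1 - 1/n_b^2)`.
#'
#' @param T Temperature (K).
#' @param m Mass (amu).
#' @param n_b Beads (>= 1).
#' @param n_samples Number of independent ring polymers.
#' @param seed RNG seed.
#' @return List with `beads` (array 3 x n_b x n_samples), `rg2`
#'   (per-sample 3-D R_g^2, nm^2), `spec`.
#' @export
sample_free_ring_polymer <- function(T, m, n_b, n_samples = 1000, seed = 1) {
  if (n_b < 1) stop("n_b must be >= 1")
  set.seed(seed)
  beads <- array(0, dim = c(3, n_b, n_samples))
  if (n_b > 1) {
    beta <- 1 / (.kB * T)
    omega <- nm_frequencies_cpp(n_b, T)
    C <- nm_matrix_cpp(n_b)
    sdk <- c(0, sqrt(n_b / (beta * m * omega[-1]^2)))
    for (i in seq_len(n_samples)) {
      q <- matrix(rnorm(3 * n_b), 3, n_b) * rep(sdk, each = 3)
      beads[, , i] <- q %*% C       # x_j = sum_k q_k C[k, j]
    }
  }
  rg2 <- apply(beads, 3, function(b) {
    c0 <- rowMeans(b)
    mean(colSums((b - c0)^2))
  })
  list(beads = beads, rg2 = rg2,
       spec = list(kind = "free_ring_polymer", T = T, m = m, n_b = n_b,
                   n_samples = n_samples, seed = seed))
}

#' Closed-form free-ring-polymer gyration radius
#'
#' Discrete-bead expression for the mean squared 3-D gyration radius,
#' `beta hbar^2 / (4 m) * (1 - 1/n_b^2)` (one third of that per
#' dimension), obtained by summing `n_b / (beta m omega_k^2)` over the
#' internal normal modes.
#'
#' @inheritParams sample_free_ring_polymer
#' @param dims Spatial dimensions (default 3).
#' @return `<R_g^2>` in nm^2.
#' @export
free_rp_rg2_closed_form <- function(T, m, n_b, dims = 3) {
  beta <- 1 / (.kB * T)
  dims * beta * .hbar^2 / (12 * m) * (1 - 1 / n_b^2)
}

#' Tetrahedral (diamond/ice-like) oxygen lattice
#'
#' Diamond-cubic O lattice (perfectly tetrahedral: q = 1 by construction)
#' with hydrogens placed along two of the four bond directions of each O.
#'
#' @param n_cells Cubic repetitions of the 8-atom conventional cell.
#' @param a Lattice constant (nm).
#' @param r_oh OH distance used for hydrogen placement (nm).
#' @return List with `O` (3 x n matrix), `positions`
#'   (array 3 x 3 x n x 1 with hydrogens), `L`,
#'   `nn_dist` (nearest-neighbour distance), `spec`.
#' @export
make_tetrahedral_lattice <- function(n_cells = 2, a = 0.45,
                                     r_oh = qtip4pf_constants()$r_eq) {
  base <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  basis <- rbind(base, sweep(base, 2, c(.25, .25, .25), "+"))
  cells <- expand.grid(i = 0:(n_cells - 1), j = 0:(n_cells - 1),
                       k = 0:(n_cells - 1))
  O <- matrix(0, 3, 8 * nrow(cells))
  idx <- 1
  for (c0 in seq_len(nrow(cells))) {
    for (b in seq_len(8)) {
      O[, idx] <- (as.numeric(cells[c0, ]) + basis[b, ]) * a
      idx <- idx + 1
    }
  }
  L <- n_cells * a
  # hydrogens along two of the four tetrahedral bond directions
  dir1 <- c(1, 1, 1) / sqrt(3)
  dir2 <- c(1, -1, -1) / sqrt(3)
  n <- ncol(O)
  pos <- array(0, dim = c(3, 3, n, 1))
  for (mcl in seq_len(n)) {
    # the two diamond sublattices bond along opposite tetrahedral axes
    sgn <- if (((mcl - 1) %% 8) < 4) 1 else -1
    pos[, 1, mcl, 1] <- O[, mcl]
    pos[, 2, mcl, 1] <- O[, mcl] + sgn * r_oh * dir1
    pos[, 3, mcl, 1] <- O[, mcl] + sgn * r_oh * dir2
  }
  list(O = O, positions = pos, L = L, nn_dist = a * sqrt(3) / 4,
       spec = list(kind = "tetrahedral_lattice", n_cells = n_cells, a = a))
}

#' Two-molecule configuration with prescribed hydrogen-bond geometry
#'
#' Builds a donor-acceptor dimer with the requested OO distance and HOO
#' angle (angle at the donor O between the donated O->X1 bond and the
#' O->O vector). The acceptor points its hydrogens away from the donor.
#'
#' @param d_oo OO distance (nm).
#' @param theta_hoo_deg HOO angle (degrees).
#' @param ff Force-field constants (monomer geometry).
#' @return Array 3 x 3 x 2 x 1.
#' @export
make_dimer <- function(d_oo, theta_hoo_deg, ff = qtip4pf_constants()) {
  th <- theta_hoo_deg * pi / 180
  pos <- array(0, dim = c(3, 3, 2, 1))
  # donor: O at origin; X1 along a direction making angle theta with +x
  # (the O->O axis), X2 placed at the equilibrium HOH angle from X1
  dirX1 <- c(cos(th), sin(th), 0)
  ang2 <- th + ff$theta_eq
  dirX2 <- c(cos(ang2), sin(ang2), 0)
  pos[, 1, 1, 1] <- c(0, 0, 0)
  pos[, 2, 1, 1] <- ff$r_eq * dirX1
  pos[, 3, 1, 1] <- ff$r_eq * dirX2
  # acceptor at (d_oo, 0, 0); its bisector (hence both hydrogens) points
  # along +x, away from the donor
  pos[, , 2, 1] <- monomer_geometry(ff) + c(d_oo, 0, 0)
  pos
}

#' Ideal-gas configurations
#'
#' Uniformly random points in a cubic box: `g(r) = 1` and `<q> -> 0`.
#'
#' @param n Points per configuration.
#' @param L Box edge (nm).
#' @param n_frames Number of configurations.
#' @param seed RNG seed.
#' @return List with `coords` (list of 3 x n matrices), `L`, `spec`.
#' @export
ideal_gas_box <- function(n, L, n_frames = 1, seed = 1) {
  set.seed(seed)
  coords <- lapply(seq_len(n_frames), function(i)
    matrix(runif(3 * n, 0, L), 3, n))
  list(coords = coords, L = L,
       spec = list(kind = "ideal_gas_box", n = n, L = L,
                   n_frames = n_frames, seed = seed))
}

# Wrap an ideal-gas fixture as a minimal archive (O-only molecules) so the
# structure pipeline cannot tell fixtures from simulations.
ideal_gas_archive <- function(n, L, n_frames = 1, seed = 1) {
  ig <- ideal_gas_box(n, L, n_frames, seed)
  fr <- array(0, dim = c(3, 3, n, 1, n_frames))
  for (f in seq_len(n_frames)) {
    fr[, 1, , 1, f] <- ig$coords[[f]]
    # token hydrogens (not used by O-channel analyses)
    fr[, 2, , 1, f] <- ig$coords[[f]] + c(0.1, 0, 0) * 0.9419e-1
    fr[, 3, , 1, f] <- ig$coords[[f]] + c(0, 0.1, 0) * 0.9419e-1
  }
  structure(list(
    meta = list(composition = "H2O", n_molecules = n,
                site_species = c("O", "H", "H"),
                site_masses = c(15.9949, 1.00783, 1.00783),
                molar_mass = 18.01056, n_b = 1L, T = 300, ensemble = "NVT",
                P = 0.1, dt = 1e-3, seed = seed, stride_est = 1L,
                stride_frame = 1L, stride_vel = 1L),
    estimators = data.frame(), frames = fr, frame_L = rep(L, n_frames),
    velocities = array(0, dim = c(3, 3 * n, 0)),
    dipoles = array(0, dim = c(3, 0)), L = L
  ), class = "trajectory_archive")
}

#' Spectral toy series
#'
#' Velocity/dipole time series that superpose cosines at prescribed
#' frequencies, packaged as a minimal `trajectory_archive` so the spectral
#' pipeline treats it exactly like a simulation. The generator refuses
#' frequencies above the Nyquist limit of the requested sampling.
#'
#' @param frequencies_cm Planted frequencies (cm^-1).
#' @param amplitudes Amplitudes, one per frequency.
#' @param dt Sampling interval (ps).
#' @param n_steps Series length.
#' @param noise_sd Additive Gaussian noise.
#' @param seed RNG seed.
#' @return A `trajectory_archive` with one atom of unit mass whose x
#'   velocity (and the x dipole) carries the signal.
#' @export
make_spectral_toy <- function(frequencies_cm, amplitudes = NULL, dt = 2e-3,
                              n_steps = 4096, noise_sd = 0, seed = 1) {
  if (is.null(amplitudes)) amplitudes <- rep(1, length(frequencies_cm))
  stopifnot(length(amplitudes) == length(frequencies_cm))
  nyq <- 1 / (2 * dt) / .c_cm_per_ps
  if (any(frequencies_cm >= nyq))
    stop(sprintf("frequency above Nyquist (%.0f cm^-1); decrease dt", nyq))
  set.seed(seed)
  t <- (seq_len(n_steps) - 1) * dt
  sig <- rep(0, n_steps)
  for (i in seq_along(frequencies_cm)) {
    om <- 2 * pi * frequencies_cm[i] * .c_cm_per_ps
    sig <- sig + amplitudes[i] * cos(om * t + runif(1, 0, 2 * pi))
  }
  if (noise_sd > 0) sig <- sig + rnorm(n_steps, sd = noise_sd)
  v <- array(0, dim = c(3, 1, n_steps))
  v[1, 1, ] <- sig
  mu <- array(0, dim = c(3, n_steps))
  mu[1, ] <- sig
  structure(list(
    meta = list(composition = "toy", n_molecules = 1L,
                site_species = "X", site_masses = 1, molar_mass = 1,
                n_b = 1L, T = 300, ensemble = "NVT", P = 0.1,
                dt = dt, seed = seed, stride_est = 1L, stride_frame = 1L,
                stride_vel = 1L),
    estimators = data.frame(), frames = array(0, c(3, 1, 1, 1, 0)),
    frame_L = numeric(), velocities = v, dipoles = mu, L = -1,
    spec = list(kind = "spectral_toy", frequencies_cm = frequencies_cm,
                amplitudes = amplitudes, dt = dt, n_steps = n_steps,
                seed = seed)
  ), class = "trajectory_archive")
}

#' Synthetic observable curves
#'
#' Generates D(T) or H(T)/E(T) tables from a named model with known
#' parameters plus multiplicative (Arrhenius/MCT) or additive (poly4)
#' Gaussian noise, for fitter-inversion tests.
#'
#' @param model `"arrhenius"` (`D0`, `E_A`), `"mct"` (`D1`, `gamma`,
#'   `T_MCT`) or `"poly4"` (`coefficients`, length 5, constant first).
#' @param params Named list of model parameters.
#' @param T Temperature grid (K).
#' @param noise Relative (arrhenius/mct) or absolute (poly4) noise level.
#' @param seed RNG seed.
#' @return data.frame `T`, `y`, `se` with attribute `spec`.
#' @export
make_curve_family <- function(model = c("arrhenius", "mct", "poly4"),
                              params, T, noise = 0, seed = 1) {
  model <- match.arg(model)
  set.seed(seed)
  y <- switch(model,
    arrhenius = params$D0 * exp(-params$E_A / (.kB * T)),
    mct = params$D1 * (T - params$T_MCT)^params$gamma,
    poly4 = drop(outer(T, 0:4, "^") %*% params$coefficients))
  if (noise > 0) {
    if (model == "poly4") {
      se <- rep(noise, length(T))
      y <- y + rnorm(length(T), sd = noise)
    } else {
      se <- abs(y) * noise
      y <- y * (1 + rnorm(length(T), sd = noise))
    }
  } else se <- rep(0, length(T))
  structure(data.frame(T = T, y = y, se = se),
            spec = list(kind = "curve_family", model = model,
                        params = params, noise = noise, seed = seed))
}
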