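# Ring-polymer propagation: settings, wrappers over the compiled engine,
# and the trajectory archive container.

#' Integrator settings
#'
#' Defaults mirror the study conditions: dt = 0.25 fs for quantum runs
#' (0.5 fs is the classical choice), PILE thermostat with centroid
#' friction gamma0 = 0.1 /ps and critically damped internal modes, and a
#' Monte Carlo barostat for NPT with ln-V proposals.
#'
#' @param n_b Number of beads per ring polymer.
#' @param dt Time step (ps). Default 2.5e-4 (0.25 fs).
#' @param ensemble `"NVT"` or `"NPT"`.
#' @param T Temperature (K).
#' @param P Target pressure (MPa) for NPT (default 0.1).
#' @param gamma0 Centroid-mode thermostat friction (1/ps) for production.
#' @param gamma0_equil Stronger centroid friction used during
#'   equilibration only, so the initial lattice thermalizes within the
#'   desk-scale run length.
#' @param pile_internal Thermostat internal modes at 2 omega_k.
#' @param thermostat Master switch; `FALSE` gives microcanonical dynamics.
#' @param n_equil,n_steps Equilibration / production step counts.
#' @param baro_every MC barostat attempt interval (steps).
#' @param baro_dlnV Half-width of the ln-V proposal.
#' @param stride_est,stride_frame,stride_vel Output strides (steps) for
#'   estimators, bead frames, and centroid velocities/dipoles.
#' @param seed RNG seed (deterministic: same seed, same trajectory).
#' @return A list of class `integrator_settings`.
#' @export
integrator_settings <- function(n_b = 8L, dt = 2.5e-4, ensemble = c("NVT", "NPT"),
                                T = 300, P = 0.1, gamma0 = 0.1,
                                gamma0_equil = 5,
                                pile_internal = TRUE, thermostat = TRUE,
                                n_equil = 2000L, n_steps = 10000L,
                                baro_every = 25L, baro_dlnV = 0.02,
                                stride_est = 10L, stride_frame = 50L,
                                stride_vel = 8L, seed = 1L) {
  ensemble <- match.arg(ensemble)
  stopifnot(dt > 0, gamma0 >= 0, n_b >= 1)
  structure(as.list(environment()), class = "integrator_settings")
}

#' Ring-polymer normal-mode transform
#'
#' Orthogonal transform between bead and normal-mode representation
#' (bead index on the last array dimension). Mode 0 is `sqrt(n_b)` times
#' the centroid; the transform round-trips to machine precision.
#'
#' @param x Array whose last dimension is the bead index.
#' @param inverse Apply the inverse (mode -> bead) transform.
#' @return Array of the same shape.
#' @export
normal_mode_transform <- function(x, inverse = FALSE) {
  d <- dim(x)
  if (is.null(d)) { d <- c(1, length(x)); dim(x) <- d }
  nb <- d[length(d)]
  C <- nm_matrix_cpp(nb)
  m <- matrix(x, ncol = nb)
  out <- if (inverse) m %*% C else m %*% t(C)
  array(out, dim = d)
}

#' Normal-mode frequencies of the free ring polymer
#'
#' `omega_k = 2 (n_b kB T / hbar) sin(k pi / n_b)`, k = 0 .. n_b-1 (rad/ps).
#'
#' @param n_b Number of beads.
#' @param T Temperature (K).
#' @return Numeric vector of length `n_b`.
#' @export
normal_mode_frequencies <- function(n_b, T) nm_frequencies_cpp(n_b, T)

run_engine <- function(state, settings, ff, potential = "qtip4pf",
                       omega_harm = 0, nsteps, stride_est, stride_frame,
                       stride_vel, seed, intra = TRUE, inter = TRUE) {
  sys <- state$system
  d <- dim(state$x)
  pimd_run_cpp(state$x, state$p, sys$site_masses, d[3], d[2], d[4], state$L,
               ff_to_cpp(ff), potential, omega_harm, state$T, settings$dt,
               as.integer(nsteps), settings$gamma0, settings$pile_internal,
               settings$thermostat, settings$ensemble, settings$P,
               as.integer(settings$baro_every), settings$baro_dlnV,
               as.integer(seed), as.integer(stride_est),
               as.integer(stride_frame), as.integer(stride_vel),
               intra, inter)
}

#' Run a PIMD/RPMD simulation
#'
#' Orchestrates equilibration followed by production and collects frames,
#' centroid velocities, total dipole moments and quantum estimators into a
#' trajectory archive. For `n_b = 1` this is classical MD.
#'
#' @param system An `isotope_system`.
#' @param settings `integrator_settings()`.
#' @param state Optional starting `rp_state`; by default a lattice box at
#'   molar volume `v` is built and bead-replicated.
#' @param v Molar volume (cm^3/mol) used when building the default box.
#' @param ff Force-field constants. If the default cutoff does not fit the
#'   box (edge < 2 r_c) the cutoff is reduced to L/2 and the reaction-field
#'   constant recomputed; the actual cutoff is recorded in the archive.
#' @return A `trajectory_archive`.
#' @export
run_simulation <- function(system, settings, state = NULL, v = 18.0,
                           ff = qtip4pf_constants()) {
  if (is.null(state)) {
    box <- water_box(system, v = v, seed = settings$seed, ff = ff)
    state <- ring_polymer_state(box$positions, system, settings$T, box$L,
                                settings$n_b, seed = settings$seed)
  }
  if (state$L > 0 && state$L < 2 * ff$r_c) ff <- ff_modify(ff, r_c = state$L / 2)
  # equilibration: strong centroid friction, no output
  if (settings$n_equil > 0) {
    eq <- settings
    eq$gamma0 <- max(settings$gamma0, settings$gamma0_equil)
    r0 <- run_engine(state, eq, ff, nsteps = settings$n_equil,
                     stride_est = 0, stride_frame = 0, stride_vel = 0,
                     seed = settings$seed)
    state$x <- r0$positions
    state$p <- r0$momenta
    state$L <- r0$L
  }
  r <- run_engine(state, settings, ff, nsteps = settings$n_steps,
                  stride_est = settings$stride_est,
                  stride_frame = settings$stride_frame,
                  stride_vel = settings$stride_vel,
                  seed = settings$seed + 1L)
  trajectory_archive(system, settings, ff, r)
}

# Assemble the archive container from an engine result.
trajectory_archive <- function(system, settings, ff, r) {
  structure(list(
    meta = list(composition = system$composition,
                n_molecules = system$n_molecules,
                site_species = system$site_species,
                site_masses = system$site_masses,
                molar_mass = system$molar_mass,
                n_b = settings$n_b, T = settings$T,
                ensemble = settings$ensemble, P = settings$P,
                dt = settings$dt, seed = settings$seed,
                gamma0 = settings$gamma0,
                r_c = ff$r_c, eps_rf = ff$eps_rf,
                ff_version = ff$version,
                stride_est = settings$stride_est,
                stride_frame = settings$stride_frame,
                stride_vel = settings$stride_vel),
    estimators = r$estimators,
    frames = r$frames, frame_L = r$frame_L,
    velocities = r$velocities, dipoles = r$dipoles,
    L = r$L,
    final = list(positions = r$positions, momenta = r$momenta),
    barostat = r$barostat
  ), class = "trajectory_archive")
}

#' @export
print.trajectory_archive <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<trajectory_archive> %s: %d molecules, n_b=%d, T=%g K, %s\n",
              m$composition, m$n_molecules, m$n_b, m$T, m$ensemble))
  cat(sprintf("  %d estimator records, %d frames, %d velocity records\n",
              nrow(x$estimators),
              if (length(dim(x$frames)) == 5) dim(x$frames)[5] else 0,
              if (length(dim(x$velocities)) == 3) dim(x$velocities)[3] else 0))
  invisible(x)
}

# time axes (ps)
archive_frame_times <- function(a) {
  dt <- a$meta$dt * a$meta$stride_frame
  n <- if (length(dim(a$frames)) == 5) dim(a$frames)[5] else 0
  seq_len(n) * dt
}
archive_vel_dt <- function(a) a$meta$dt * a$meta$stride_vel

#' Quantum estimators of a state
#'
#' Single-configuration evaluation of the estimator record: bead-averaged
#' potential, primitive and centroid-virial kinetic estimators, virial
#' pressure, total quantum energy `E = K_cv + U` and (for NPT) enthalpy
#' `H = E + P V`. For `n_b = 1` the kinetic estimators reduce to the
#' classical kinetic energy.
#'
#' @param state An `rp_state`.
#' @param ff Force-field constants.
#' @param potential `"qtip4pf"`, `"harmonic"` or `"none"`.
#' @param omega_harm Oscillator angular frequency (rad/ps) for `"harmonic"`.
#' @param P Target pressure (MPa) used to form the enthalpy.
#' @return Named list (kJ/mol per system): `U`, `K_prim`, `K_cv`, `E`,
#'   `H`, `P_virial` (MPa), `V` (nm^3).
#' @export
quantum_estimators <- function(state, ff = qtip4pf_constants(),
                               potential = "qtip4pf", omega_harm = 0,
                               P = 0.1) {
  sys <- state$system
  d <- dim(state$x)
  nb <- d[4]; nmol <- d[3]; nsite <- d[2]
  if (potential == "qtip4pf") {
    if (state$L > 0 && state$L < 2 * ff$r_c)
      ff <- ff_modify(ff, r_c = state$L / 2)
    ev <- total_potential(state$x, state$L, ff)
  } else if (potential == "harmonic") {
    U <- 0; Fv <- array(0, dim = d); W <- 0
    for (s in seq_len(nsite)) {
      msw <- sys$site_masses[s] * omega_harm^2
      xs <- state$x[, s, , , drop = FALSE]
      U <- U + 0.5 * msw * sum(xs^2)
      Fv[, s, , ] <- -msw * xs
    }
    ev <- list(energy = rep(U / nb, nb), forces = Fv, virial = rep(0, nb))
  } else {
    ev <- list(energy = rep(0, nb), forces = array(0, dim = d),
               virial = rep(0, nb))
  }
  kT <- .kB * state$T
  natom <- nmol * nsite
  U <- sum(ev$energy) / nb
  if (nb == 1) {
    # classical collapse: both kinetic estimators are the kinetic energy
    K_cv <- K_prim <- sum(sapply(seq_len(nsite), function(s)
      sum(state$p[, s, , ]^2) / (2 * sys$site_masses[s])))
  } else {
    xc <- apply(state$x, c(1, 2, 3), mean)
    dev <- sweep(state$x, c(1, 2, 3), xc)
    K_cv <- 1.5 * natom * kT - sum(dev * ev$forces) / (2 * nb)
    wn <- nb * kT / .hbar
    xs <- state$x
    xnext <- xs[, , , c(2:nb, 1), drop = FALSE]
    spr <- 0
    for (s in seq_len(nsite))
      spr <- spr + 0.5 * sys$site_masses[s] * wn^2 *
        sum((xnext[, s, , ] - xs[, s, , ])^2)
    K_prim <- 1.5 * natom * nb * kT - spr / nb
  }
  V <- if (state$L > 0) state$L^3 else NA_real_
  P_vir <- if (is.finite(V))
    (2 * K_cv + sum(ev$virial) / nb) / (3 * V) * .kj_nm3_to_MPa else NA_real_
  E <- K_cv + U
  H <- if (is.finite(V)) E + P / .kj_nm3_to_MPa * V else NA_real_
  list(U = U, K_prim = K_prim, K_cv = K_cv, E = E, H = H,
       P_virial = P_vir, V = V)
}

#' Simulate independent particles (free or harmonic)
#'
#' Runs the ring-polymer engine for a system of non-interacting atoms in a
#' free or isotropic-harmonic external potential. Used to validate the
#' propagator and estimators against closed-form quantum results.
#'
#' @param mass Particle mass (amu).
#' @param n_particles Number of independent particles.
#' @param n_b Beads.
#' @param T Temperature (K).
#' @param potential `"none"` or `"harmonic"`.
#' @param omega Angular frequency (rad/ps) of the harmonic well.
#' @param settings Optional `integrator_settings` overrides (dt, strides...).
#' @param n_steps,n_equil Production / equilibration steps.
#' @param seed RNG seed.
#' @return List with `estimators` (data.frame), `frames`
#'   (3 x 1 x n_particles x n_b x n_frames) and the final state.
#' @export
simulate_particles <- function(mass, n_particles = 1, n_b = 16, T = 300,
                               potential = c("none", "harmonic"), omega = 0,
                               n_steps = 20000, n_equil = 2000,
                               dt = 5e-4, stride_est = 5L, stride_frame = 10L,
                               gamma0 = NULL, seed = 1) {
  potential <- match.arg(potential)
  if (is.null(gamma0)) gamma0 <- if (potential == "none") 5 else omega
  sys <- structure(list(composition = "atoms",
                        n_molecules = as.integer(n_particles),
                        site_species = "X", site_masses = mass,
                        molar_mass = mass), class = "isotope_system")
  x <- array(0, dim = c(3, 1, n_particles, n_b))
  st <- list(x = x, p = x, L = -1, T = T, n_b = n_b, system = sys)
  set.seed(seed)
  st$p <- array(rnorm(length(x), sd = sqrt(mass * n_b * .kB * T)), dim = dim(x))
  settings <- integrator_settings(n_b = n_b, dt = dt, T = T, gamma0 = gamma0,
                                  seed = as.integer(seed))
  if (n_equil > 0) {
    r0 <- run_engine(st, settings, qtip4pf_constants(), potential = potential,
                     omega_harm = omega, nsteps = n_equil, stride_est = 0,
                     stride_frame = 0, stride_vel = 0, seed = seed)
    st$x <- r0$positions; st$p <- r0$momenta
  }
  r <- run_engine(st, settings, qtip4pf_constants(), potential = potential,
                  omega_harm = omega, nsteps = n_steps,
                  stride_est = stride_est, stride_frame = stride_frame,
                  stride_vel = 0, seed = seed + 1)
  list(estimators = r$estimators, frames = r$frames,
       final = list(positions = r$positions, momenta = r$momenta))
}
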