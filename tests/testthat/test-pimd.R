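# Ring-polymer propagator: normal modes, sampling against closed forms,
# classical collapse, barostat, estimators, determinism.

pc <- physical_constants()

test_that("normal-mode transform is orthogonal with centroid mode 0", {
  for (nb in c(1, 2, 4, 7, 16)) {
    C <- pimdwater:::nm_matrix_cpp(nb)
    expect_equal(C %*% t(C), diag(nb), tolerance = 1e-12)
    x <- array(rnorm(3 * 2 * 5 * nb), dim = c(3, 2, 5, nb))
    xr <- normal_mode_transform(normal_mode_transform(x), inverse = TRUE)
    expect_equal(xr, x, tolerance = 1e-12)
    # all beads equal -> only mode 0 nonzero
    xe <- array(rep(rnorm(3 * 2 * 5), nb), dim = c(3, 2, 5, nb))
    xm <- normal_mode_transform(xe)
    if (nb > 1) expect_equal(max(abs(xm[, , , -1])), 0, tolerance = 1e-12)
    expect_equal(xm[, , , 1], xe[, , , 1] * sqrt(nb), tolerance = 1e-12)
  }
})

test_that("mode frequencies match direct diagonalization of the bead coupling", {
  for (nb in c(2, 5, 8, 32)) {
    T <- 260
    w <- normal_mode_frequencies(nb, T)
    beta <- 1 / (pc$kB * T)
    wn <- nb / (beta * pc$hbar)
    ev <- sort(eigen(wn^2 * ring_coupling_matrix(nb), symmetric = TRUE)$values)
    ev[ev < 1e-8 * max(ev)] <- 0       # numerical zero of the centroid mode
    lam <- sqrt(pmax(0, ev))
    expect_equal(sort(w), lam, tolerance = 1e-9)
  }
})

test_that("free ring polymer samples the closed-form R_g^2 (engine route)", {
  # also checks the brute-force normal-mode summation against the
  # analytic discrete expression
  for (nb in c(4, 16)) {
    expect_equal(rg2_brute_force(300, 1.00783, nb),
                 free_rp_rg2_closed_form(300, 1.00783, nb), tolerance = 1e-10)
  }
  r <- simulate_particles(1.00783, n_particles = 8, n_b = 16, T = 300,
                          potential = "none", n_steps = 12000,
                          n_equil = 2000, dt = 5e-4, stride_frame = 20,
                          seed = 7)
  d <- dim(r$frames)
  rg2 <- sapply(seq_len(d[5]), function(f) {
    x <- array(r$frames[, , , , f], d[1:4])
    mean(sapply(seq_len(d[3]), function(m) {
      b <- x[, 1, m, ]
      mean(colSums((b - rowMeans(b))^2))
    }))
  })
  nblk <- 10
  bm <- tapply(rg2, rep(seq_len(nblk), length.out = length(rg2)), mean)
  se <- sd(bm) / sqrt(nblk)
  expect_lt(abs(mean(rg2) - rg2_brute_force(300, 1.00783, 16)), 3 * se)
})

test_that("harmonic oscillator energy matches the finite-bead closed form", {
  T <- 300; m <- 1; om <- 50
  r <- simulate_particles(m, n_particles = 16, n_b = 16, T = T,
                          potential = "harmonic", omega = om,
                          n_steps = 60000, n_equil = 6000, dt = 2e-4,
                          stride_est = 5, stride_frame = 0, seed = 11)
  E <- (r$estimators$K_cv + r$estimators$U) / 16
  bm <- tapply(E, rep(1:12, length.out = length(E)), mean)
  se <- sd(bm) / sqrt(12)
  expect_lt(abs(mean(E) - ho_energy_exact(T, m, om, 16)),
            max(3 * se, 0.01 * mean(E)))
  # primitive and centroid-virial kinetic estimators agree on average
  Kp <- mean(r$estimators$K_prim) / 16
  Kc <- mean(r$estimators$K_cv) / 16
  expect_lt(abs(Kp - Kc), max(6 * se, 0.02 * Kc))
})

test_that("n_b = 1 harmonic run gives the classical equipartition energy", {
  T <- 300; om <- 50
  r <- simulate_particles(1, n_particles = 16, n_b = 1, T = T,
                          potential = "harmonic", omega = om,
                          n_steps = 60000, n_equil = 6000, dt = 2e-4,
                          stride_est = 5, stride_frame = 0, seed = 3)
  E <- (r$estimators$K_cv + r$estimators$U) / 16
  bm <- tapply(E, rep(1:12, length.out = length(E)), mean)
  se <- sd(bm) / sqrt(12)
  expect_lt(abs(mean(E) - 3 * pc$kB * T), max(3 * se, 0.01 * mean(E)))
  # with one bead the two kinetic estimators are identical
  expect_equal(r$estimators$K_cv, r$estimators$K_prim, tolerance = 1e-10)
})

test_that("thermostat-off n_b=1 engine is velocity-Verlet (independent oracle)", {
  ff <- qtip4pf_constants()
  sys <- isotope_system("H2O", 2)
  box <- water_box(sys, L = 1.2, seed = 4)
  st <- ring_polymer_state(box$positions, sys, 300, -1, 1, seed = 5)
  set <- integrator_settings(n_b = 1, dt = 2.5e-4, T = 300, gamma0 = 0,
                             thermostat = FALSE, pile_internal = FALSE)
  nst <- 200
  r <- pimdwater:::run_engine(st, set, ff, nsteps = nst, stride_est = 0,
                              stride_frame = 0, stride_vel = 0, seed = 1)
  # R-side velocity-Verlet with the same force routine
  x <- st$x; p <- st$p
  m3 <- rep(sys$site_masses, each = 3)
  f <- array(total_potential(x, -1, ff)$forces, dim = dim(x))
  for (i in seq_len(nst)) {
    p <- p + 0.5 * set$dt * f
    for (s in 1:3) x[, s, , ] <- x[, s, , ] + set$dt * p[, s, , ] / sys$site_masses[s]
    f <- array(total_potential(x, -1, ff)$forces, dim = dim(x))
    p <- p + 0.5 * set$dt * f
  }
  expect_equal(as.numeric(r$positions), as.numeric(x), tolerance = 1e-12)
  expect_equal(as.numeric(r$momenta), as.numeric(p), tolerance = 1e-12)
})

test_that("microcanonical energy drift shrinks as dt^2 on a monomer", {
  ff <- qtip4pf_constants()
  sys <- isotope_system("H2O", 1)
  x0 <- array(pimdwater:::monomer_geometry(ff), dim = c(3, 3, 1, 1))
  x0[1, 2, 1, 1] <- x0[1, 2, 1, 1] + 0.005    # small stretch excitation
  drift <- sapply(c(1e-4, 5e-5), function(dt) {
    st <- ring_polymer_state(x0, sys, 10, -1, 1, seed = 6)
    set <- integrator_settings(n_b = 1, dt = dt, T = 10, gamma0 = 0,
                               thermostat = FALSE)
    nst <- round(0.05 / dt)
    r <- pimdwater:::run_engine(st, set, ff, nsteps = nst, stride_est = 10,
                                stride_frame = 0, stride_vel = 0, seed = 1)
    e <- r$estimators$K_cv + r$estimators$U
    max(abs(e - e[1]))
  })
  expect_lt(drift[2], drift[1] / 2)   # better than linear; ~4x for O(dt^2)
  expect_lt(drift[1], 0.5)            # kJ/mol on a ~6 kJ/mol excitation
})

test_that("identical seeds give bit-identical trajectories", {
  sys <- isotope_system("D2O", 4)
  set <- integrator_settings(n_b = 4, T = 280, n_equil = 100L,
                             n_steps = 300L, seed = 42L,
                             stride_est = 10L, stride_frame = 50L)
  a1 <- run_simulation(sys, set, v = 18.0)
  a2 <- run_simulation(sys, set, v = 18.0)
  expect_identical(a1$final$positions, a2$final$positions)
  expect_identical(a1$estimators, a2$estimators)
})

test_that("MC barostat reproduces the ideal-gas volume law", {
  sys <- isotope_system("H2O", 16)
  box <- water_box(sys, L = 2, seed = 1)
  st <- ring_polymer_state(box$positions, sys, 300, 2, 1, seed = 2)
  set <- integrator_settings(n_b = 1, dt = 5e-4, ensemble = "NPT", T = 300,
                             P = 5, gamma0 = 2, baro_every = 10,
                             baro_dlnV = 0.15, seed = 5)
  r <- pimdwater:::run_engine(st, set, qtip4pf_constants(),
                              potential = "none", nsteps = 40000,
                              stride_est = 10, stride_frame = 0,
                              stride_vel = 0, seed = 5)
  V <- r$estimators$V
  Vexp <- (16 + 1) * pc$kB * 300 * pc$kJ_nm3_to_MPa / 5
  bm <- tapply(V, rep(1:10, length.out = length(V)), mean)
  se <- sd(bm) / sqrt(10)
  expect_lt(abs(mean(V) - Vexp), max(4 * se, 0.015 * Vexp))
  acc <- r$barostat["accepted"] / r$barostat["attempts"]
  expect_gt(acc, 0); expect_lt(acc, 1)
})

test_that("zero-width volume proposals leave the state unchanged", {
  sys <- isotope_system("H2O", 8)
  set <- integrator_settings(n_b = 1, ensemble = "NPT", T = 300, P = 0.1,
                             baro_dlnV = 0, baro_every = 5,
                             n_equil = 0L, n_steps = 200L, seed = 9)
  a <- run_simulation(sys, set)
  expect_equal(var(a$estimators$V), 0)
})

test_that("centroid kinetic temperature equilibrates to the target", {
  sys <- isotope_system("H2O", 8)
  set <- integrator_settings(n_b = 4, T = 300, n_equil = 4000L,
                             n_steps = 6000L, seed = 21, gamma0 = 2,
                             stride_est = 5L)
  a <- run_simulation(sys, set)
  expect_lt(abs(mean(a$estimators$T_centroid) - 300) / 300, 0.15)
})

test_that("instability aborts with a diagnostic", {
  sys <- isotope_system("H2O", 2)
  box <- water_box(sys, L = 1.2, seed = 4)
  st <- ring_polymer_state(box$positions, sys, 300, -1, 1, seed = 5)
  st$p <- st$p * 2000                       # absurd momenta
  set <- integrator_settings(n_b = 1, dt = 5e-3, T = 300, thermostat = FALSE,
                             gamma0 = 0)
  expect_error(
    pimdwater:::run_engine(st, set, qtip4pf_constants(), nsteps = 50,
                           stride_est = 0, stride_frame = 0,
                           stride_vel = 0, seed = 1),
    "instability|non-finite|degenerate|overlapping")
})

test_that("quantum estimators reduce to classical values at n_b = 1", {
  sys <- isotope_system("H2O", 4)
  box <- water_box(sys, L = 1.6, seed = 8)
  st <- ring_polymer_state(box$positions, sys, 300, 1.6, 1, seed = 3)
  est <- quantum_estimators(st, qtip4pf_constants())
  ke <- 0
  for (s in 1:3) ke <- ke + sum(st$p[, s, , ]^2) / (2 * sys$site_masses[s])
  # both estimators collapse to the classical kinetic energy
  expect_equal(est$K_prim, ke, tolerance = 1e-10)
  expect_equal(est$K_cv, ke, tolerance = 1e-10)
})
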