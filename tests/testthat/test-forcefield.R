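# q-TIP4P/F potential: closed-form limits, gradient consistency,
# symmetries, and the reaction-field kernel.

ff <- qtip4pf_constants()

test_that("constants file is internally consistent", {
  expect_equal(ff$q_M, -2 * ff$q_H)
  expect_true(all(ff$masses > 0))
  expect_equal(ff$r_c, 1.0)
  expect_equal(ff$eps_rf, 78.3)
})

test_that("monomer at the expansion minimum has zero energy and forces", {
  x0 <- array(pimdwater:::monomer_geometry(ff), dim = c(3, 3, 1, 1))
  ev <- total_potential(x0, -1, ff)
  expect_equal(sum(ev$energy), 0, tolerance = 1e-12)
  expect_equal(max(abs(ev$forces)), 0, tolerance = 1e-12)
})

test_that("small bond stretch reproduces the harmonic limit D a^2 d^2", {
  for (dlt in c(1e-4, 5e-5)) {
    x <- array(pimdwater:::monomer_geometry(ff), dim = c(3, 3, 1, 1))
    u <- x[, 2, 1, 1] / sqrt(sum(x[, 2, 1, 1]^2))
    x[, 2, 1, 1] <- x[, 2, 1, 1] + dlt * u
    E <- sum(intramolecular_energy_forces(x, ff = ff)$energy)
    # cubic correction enters at relative order alpha_r * delta
    expect_equal(E, ff$D_r * ff$alpha_r^2 * dlt^2,
                 tolerance = 2 * ff$alpha_r * dlt)
  }
})

test_that("forces are exact negative gradients (all terms, random configs)", {
  set.seed(42)
  sys <- isotope_system("H2O", 6)
  box <- water_box(sys, L = 2.2, seed = 7)
  for (rep in 1:3) {
    x <- box$positions + array(rnorm(length(box$positions), sd = 0.004),
                               dim = dim(box$positions))
    ev <- total_potential(x, 2.2, ff)
    efun <- function(xx) sum(total_potential(xx, 2.2, ff)$energy)
    idx <- sample(length(x), 10)
    for (i in idx) {
      h <- 1e-5
      xp <- x; xp[i] <- xp[i] + h
      xm <- x; xm[i] <- xm[i] - h
      fnum <- -(efun(xp) - efun(xm)) / (2 * h)
      expect_equal(ev$forces[i], fnum,
                   tolerance = 1e-6 * max(1, abs(fnum)))
    }
  }
})

test_that("two molecules beyond the cutoff do not interact", {
  pos <- array(0, dim = c(3, 3, 2, 1))
  pos[, , 1, 1] <- pimdwater:::monomer_geometry(ff)
  pos[, , 2, 1] <- pimdwater:::monomer_geometry(ff) + c(1.2, 0, 0)
  ev <- intermolecular_energy_forces(pos, L = 4, ff = ff)
  expect_equal(sum(ev$energy), 0)
  expect_equal(max(abs(ev$forces)), 0)
})

test_that("Coulomb term matches the hand-evaluated reaction-field kernel", {
  # dimer: sum the shifted RF kernel over all 9 charged site pairs by
  # hand (plus the LJ O-O term) and compare with the evaluator
  pos <- make_dimer(0.30, 15, ff)
  g <- ff$m_site_weight
  sites <- function(m) {
    O <- pos[, 1, m, 1]; X1 <- pos[, 2, m, 1]; X2 <- pos[, 3, m, 1]
    M <- g * O + (1 - g) / 2 * (X1 + X2)
    list(p = cbind(X1, X2, M), q = c(ff$q_H, ff$q_H, ff$q_M), O = O)
  }
  s1 <- sites(1); s2 <- sites(2)
  e_hand <- 0
  for (a in 1:3) for (b in 1:3) {
    r <- sqrt(sum((s1$p[, a] - s2$p[, b])^2))
    e_hand <- e_hand + rf_pair_energy(r, s1$q[a], s2$q[b], ff$r_c, ff$eps_rf)
  }
  roo <- sqrt(sum((s1$O - s2$O)^2))
  sr6 <- (ff$sigma / roo)^6
  e_hand <- e_hand + 4 * ff$epsilon * (sr6^2 - sr6)
  ev <- intermolecular_energy_forces(pos, L = -1, ff = ff)
  expect_equal(sum(ev$energy), e_hand, tolerance = 1e-10)
})

test_that("LJ closed-form values at sigma and the minimum", {
  # two molecules with only O-O in range; zero charges isolate LJ
  ff0 <- ff_modify(ff, q_H = 0, q_M = 0)
  for (case in list(c(ff$sigma, 0), c(2^(1 / 6) * ff$sigma, -ff$epsilon))) {
    pos <- array(0, dim = c(3, 3, 2, 1))
    pos[, , 1, 1] <- pimdwater:::monomer_geometry(ff)
    pos[, , 2, 1] <- pimdwater:::monomer_geometry(ff)
    pos[1, , 2, 1] <- pos[1, , 2, 1] + case[1]
    ev <- intermolecular_energy_forces(pos, L = -1, ff = ff0)
    expect_equal(sum(ev$energy), case[2], tolerance = 1e-10)
  }
})

test_that("M site sits on the bisector and coincides with O at weight 1", {
  x0 <- array(pimdwater:::monomer_geometry(ff), dim = c(3, 3, 1, 1))
  m <- m_site_geometry(x0, ff = ff)
  # bisector of the reference monomer is +x, and y component vanishes
  expect_equal(m$m_positions[2, 1, 1], 0, tolerance = 1e-12)
  expect_equal(m$m_positions[3, 1, 1], 0, tolerance = 1e-12)
  expect_true(m$m_positions[1, 1, 1] > 0)
  m1 <- m_site_geometry(x0, ff = ff_modify(ff, m_site_weight = 1))
  expect_equal(m1$m_positions[, 1, 1], x0[, 1, 1, 1], tolerance = 1e-14)
})

test_that("force redistribution conserves total force and torque", {
  set.seed(1)
  sys <- isotope_system("H2O", 4)
  box <- water_box(sys, L = 1.6, seed = 3)
  x <- box$positions
  ev <- total_potential(x, -1, ff)   # isolated cluster: exact conservation
  Ftot <- apply(ev$forces, 1, sum)
  expect_equal(max(abs(Ftot)), 0, tolerance = 1e-10)
  # torque about the origin
  tau <- c(0, 0, 0)
  for (m in 1:4) for (s in 1:3) {
    r <- x[, s, m, 1]; f <- ev$forces[, s, m, 1]
    tau <- tau + c(r[2] * f[3] - r[3] * f[2],
                   r[3] * f[1] - r[1] * f[3],
                   r[1] * f[2] - r[2] * f[1])
  }
  expect_equal(max(abs(tau)), 0, tolerance = 1e-9)
})

test_that("energy is invariant under rigid translation and rotation", {
  sys <- isotope_system("H2O", 4)
  box <- water_box(sys, L = 1.6, seed = 5)
  x <- box$positions
  e0 <- sum(total_potential(x, -1, ff)$energy)
  xt <- x + 0.37
  expect_equal(sum(total_potential(xt, -1, ff)$energy), e0, tolerance = 1e-10)
  R <- pimdwater:::random_rotation()
  xr <- x
  for (m in 1:4) for (s in 1:3) xr[, s, m, 1] <- R %*% x[, s, m, 1]
  expect_equal(sum(total_potential(xr, -1, ff)$energy), e0, tolerance = 1e-9)
})

test_that("coinciding bead slices give identical per-bead energies", {
  sys <- isotope_system("H2O", 4)
  box <- water_box(sys, L = 1.6, seed = 9)
  x4 <- array(rep(box$positions, 4), dim = c(3, 3, 4, 4))
  ev <- total_potential(x4, -1, ff)
  expect_equal(ev$energy, rep(ev$energy[1], 4), tolerance = 1e-12)
})

test_that("isotope substitution changes nothing at fixed coordinates", {
  box <- water_box(isotope_system("H2O", 4), L = 1.6, seed = 2)
  us <- sapply(c("H2O", "HDO", "D2O", "T2O"), function(comp) {
    sys <- isotope_system(comp, 4)
    st <- ring_polymer_state(box$positions, sys, 300, -1, 1, seed = 1)
    quantum_estimators(st, ff)$U
  })
  expect_equal(max(us) - min(us), 0, tolerance = 1e-12)
})

test_that("invalid geometries are rejected", {
  x <- array(pimdwater:::monomer_geometry(ff), dim = c(3, 3, 1, 1))
  x[1, 1, 1, 1] <- NaN
  expect_error(total_potential(x, -1, ff), "non-finite")
  y <- array(0, dim = c(3, 3, 1, 1))       # zero bond length
  expect_error(total_potential(y, -1, ff), "degenerate")
})

test_that("overlapping charged sites are rejected", {
  pos <- array(0, dim = c(3, 3, 2, 1))
  pos[, , 1, 1] <- pimdwater:::monomer_geometry(ff)
  pos[, , 2, 1] <- pos[, , 1, 1]
  pos[, 1, 2, 1] <- pos[, 1, 2, 1] + c(2e-5, 0, 0)
  pos[, 2, 2, 1] <- pos[, 2, 1, 1] + c(2e-5, 0, 0)
  pos[, 3, 2, 1] <- pos[, 3, 1, 1] + c(2e-5, 0, 0)
  expect_error(intermolecular_energy_forces(pos, L = -1, ff = ff),
               "overlapping")
})

test_that("monomer harmonic frequencies follow the reduced-mass scaling", {
  fH <- monomer_normal_modes(isotope_system("H2O"))$frequencies_cm
  fD <- monomer_normal_modes(isotope_system("D2O"))$frequencies_cm
  ratio <- mean(tail(fH, 2)) / mean(tail(fD, 2))
  expect_equal(ratio, stretch_ratio_oracle(), tolerance = 0.01)
})
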