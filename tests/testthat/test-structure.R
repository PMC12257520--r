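# Structure operators: RDF normalization, tetrahedral order, shell
# separation, hydrogen bonds, gyration decomposition.

test_that("ideal-gas RDF is unity within noise", {
  a <- pimdwater:::ideal_gas_archive(120, L = 3, n_frames = 12, seed = 1)
  g <- rdf(a, "OO", bins = 25, r_max = 1.4)
  sel <- g$r > 0.35           # small-r bins hold few ideal-gas pairs
  expect_lt(max(abs(g$g[sel] - 1)), 0.25)
  expect_lt(abs(mean(g$g[sel]) - 1), 0.05)
})

test_that("two fixed atoms in a large box give one normalized RDF spike", {
  r0 <- 0.53            # mid-bin, away from histogram edges
  fr <- array(0, dim = c(3, 3, 2, 1, 1))
  fr[, 1, 2, 1, 1] <- c(r0, 0, 0)
  fr[, 2, , 1, 1] <- fr[, 1, , 1, 1] + c(5, 5, 5)  # hydrogens far away
  fr[, 3, , 1, 1] <- fr[, 1, , 1, 1] - c(5, 5, 5)
  a <- pimdwater:::ideal_gas_archive(2, L = 12, n_frames = 1)
  a$frames <- fr
  a$frame_L <- 12
  bins <- 24; rmax <- 1.2
  g <- rdf(a, "OO", bins = bins, r_max = rmax)
  i <- findInterval(r0, seq(0, rmax, length.out = bins + 1))
  # hand normalization: the single pair lands in bin i with ideal-gas
  # probability shell/V, so g = V/shell there
  edges <- seq(0, rmax, length.out = bins + 1)
  shell <- 4 / 3 * pi * (edges[i + 1]^3 - edges[i]^3)
  expect_equal(g$g[i], 12^3 / shell, tolerance = 1e-9)
  expect_equal(sum(g$g > 0), 1)
})

test_that("rdf rejects r_max beyond half the box", {
  a <- pimdwater:::ideal_gas_archive(20, L = 2, n_frames = 1)
  expect_error(rdf(a, "OO", r_max = 1.5), "L/2")
})

test_that("tetrahedral lattice gives q = 1 exactly; random gas gives q near 0", {
  lat <- make_tetrahedral_lattice(2, a = 0.45)
  q <- tetrahedral_q(lat$O, L = lat$L)
  expect_equal(q$q_mean, 1, tolerance = 1e-10)
  ig <- ideal_gas_box(300, L = 3, seed = 2)
  q0 <- tetrahedral_q(ig$coords[[1]], L = 3)
  expect_lt(abs(q0$q_mean), 0.12)
})

test_that("perturbing one neighbour reproduces the hand-computed q", {
  lat <- make_tetrahedral_lattice(2, a = 0.45)
  O <- lat$O
  # rotate one first-shell neighbour of molecule 1 by a known angle
  dm <- pimdwater:::pair_dists(O, L = lat$L)
  diag(dm) <- Inf
  j <- order(dm[1, ])[1]
  v <- O[, j] - O[, 1]
  v <- v - lat$L * round(v / lat$L)
  eps <- 0.06
  perp <- c(v[2], -v[1], 0); perp <- perp / sqrt(sum(perp^2))
  O[, j] <- O[, 1] + v + eps * perp
  qv <- tetrahedral_q(O, L = lat$L)$q[1]
  # hand evaluation of q for molecule 1 from its (new) neighbour vectors
  dm2 <- pimdwater:::pair_dists(O, L = lat$L)
  diag(dm2) <- Inf
  nb4 <- order(dm2[1, ])[1:4]
  U <- sapply(nb4, function(jj) {
    w <- O[, jj] - O[, 1]
    w <- w - lat$L * round(w / lat$L)
    w / sqrt(sum(w^2))
  })
  s <- 0
  for (a in 1:3) for (b in (a + 1):4)
    s <- s + (sum(U[, a] * U[, b]) + 1 / 3)^2
  expect_equal(qv, 1 - 3 / 8 * s, tolerance = 1e-12)
  expect_lt(qv, 1)   # perturbation strictly decreases q
})

test_that("shell separation on a constructed two-shell geometry", {
  # 4 neighbours at r1, next neighbours at r2: dfs = r2 - r1 for the
  # central molecule
  r1 <- 0.28; r2 <- 0.42
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  shell1 <- t(dirs) * r1
  shell2 <- cbind(c(r2, 0, 0), c(0, r2, 0), c(0, 0, r2), c(-r2, 0, 0))
  O <- cbind(c(0, 0, 0), shell1, shell2)
  d <- dfs_metric(O, L = -1)
  expect_equal(d$dfs[1], r2 - r1, tolerance = 1e-12)
  # an interstitial between the shells shrinks the gap
  Oi <- cbind(O, c(0.35, 0, 0))
  di <- dfs_metric(Oi, L = -1)
  expect_lt(di$dfs[1], d$dfs[1])
  # equidistant neighbours -> zero separation
  Oe <- cbind(c(0, 0, 0), t(dirs) * r1, c(r1, 0, 0), c(0, r1, 0))
  expect_equal(dfs_metric(Oe, L = -1)$dfs[1], 0, tolerance = 1e-12)
})

test_that("dimer fixtures hit both sides of the HB criterion", {
  crit <- hb_criteria()
  hb1 <- detect_hbonds(array(make_dimer(0.34, 20), c(3, 3, 2)), -1, crit)
  expect_equal(nrow(hb1), 1)
  expect_equal(hb1$d_oo, 0.34, tolerance = 1e-12)
  expect_equal(hb1$theta_deg, 20, tolerance = 1e-9)
  hb2 <- detect_hbonds(array(make_dimer(0.36, 5), c(3, 3, 2)), -1, crit)
  expect_equal(nrow(hb2), 0)     # distance fails
  hb3 <- detect_hbonds(array(make_dimer(0.30, 35), c(3, 3, 2)), -1, crit)
  expect_equal(nrow(hb3), 0)     # angle fails
})

test_that("HB detector matches the brute-force O(N^2) oracle on 16 molecules", {
  set.seed(6)
  sys <- isotope_system("H2O", 16)
  for (seed in c(3, 9)) {
    box <- water_box(sys, v = 18, seed = seed, jitter = 0.02)
    coords <- array(box$positions[, , , 1], c(3, 3, 16))
    hb <- detect_hbonds(coords, box$L)
    oracle <- hb_brute_force(coords, box$L)
    expect_equal(nrow(hb), oracle$n)
    if (nrow(hb) > 0) {
      got <- apply(hb[, c("donor", "site", "acceptor")], 1, paste,
                   collapse = "-")
      want <- vapply(oracle$bonds, paste, "", collapse = "-")
      expect_setequal(got, want)
    }
  }
})

test_that("replica-constructed HB statistics equal the hand average", {
  # two beads holding two different dimer geometries
  fr <- array(0, dim = c(3, 3, 2, 2, 1))
  fr[, , , 1, 1] <- make_dimer(0.30, 10)[, , , 1]
  fr[, , , 2, 1] <- make_dimer(0.33, 22)[, , , 1]
  a <- pimdwater:::ideal_gas_archive(2, L = 10, n_frames = 1)
  a$frames <- fr
  a$frame_L <- 10
  a$meta$n_b <- 2L
  st <- hb_geometry_stats(a)
  expect_equal(st$d_oo_mean, mean(c(3.0, 3.3)), tolerance = 1e-9)
  expect_equal(st$theta_mean, mean(c(10, 22)), tolerance = 1e-7)
  expect_equal(st$n_hb_per_molecule, 1)   # 1 bond over 2 molecules, x2
})

test_that("hb_energy follows the defining arithmetic and guards mismatches", {
  mk <- function(U, N, T = 300, nb = 2L, comp = "H2O") {
    a <- pimdwater:::ideal_gas_archive(2, L = 10, n_frames = 1)
    a$estimators <- data.frame(step = 1:10, U = U)
    a$meta$n_molecules <- N
    a$meta$T <- T; a$meta$n_b <- nb; a$meta$composition <- comp
    fr <- array(0, dim = c(3, 3, 2, nb, 1))
    for (k in seq_len(nb)) fr[, , , k, 1] <- make_dimer(0.30, 10)[, , , 1]
    a$frames <- fr; a$frame_L <- 10
    a
  }
  liquid <- mk(U = rep(-20, 10), N = 2)       # per molecule: -10
  mono <- mk(U = rep(2, 10), N = 1)
  # n_hb = 2 * 1 bond / 2 molecules = 1; E_HB = (-10 - 2)/1
  eh <- hb_energy(liquid, mono)
  expect_equal(eh$E_HB, -12)
  expect_equal(eh$n_hb, 1)
  mono_bad <- mk(U = rep(2, 10), N = 1, T = 250)
  expect_error(hb_energy(liquid, mono_bad), "match")
})

test_that("gyration: n_b = 1 gives zero; free-particle beads match closed form", {
  # classical archive
  ig <- pimdwater:::ideal_gas_archive(6, L = 3, n_frames = 2, seed = 3)
  g1 <- gyration_analysis(ig)
  expect_true(all(g1$R_g == 0))
  # free ring-polymer fixture wrapped as frames of an archive
  T <- 250; m <- 1.00783; nb <- 12
  s <- sample_free_ring_polymer(T, m, nb, n_samples = 4000, seed = 8)
  cf <- free_rp_rg2_closed_form(T, m, nb)
  se <- sd(s$rg2) / sqrt(length(s$rg2))
  expect_lt(abs(mean(s$rg2) - cf), 3 * se)
})

test_that("gyration components sum to the total exactly and are isotropic for O", {
  a <- desk_run("H2O")
  g <- gyration_analysis(a)
  comps <- g$R_g2_components
  expect_equal(comps$Rg2_x + comps$Rg2_y + comps$Rg2_z, comps$Rg2,
               tolerance = 1e-10)
  orow <- comps[comps$species == "O", ][1, ]
  spread <- max(orow$Rg2_x, orow$Rg2_y, orow$Rg2_z) /
    min(orow$Rg2_x, orow$Rg2_y, orow$Rg2_z)
  expect_lt(spread, 1.35)   # O delocalization is isotropic
})

test_that("liquid RDF integrates to about N-1 neighbours over the box", {
  a <- desk_run("H2O")
  g <- rdf(a, "OO", bins = 40)
  rho <- 32 / mean(a$frame_L^3)
  integral <- sum(4 * pi * rho * g$g * g$r^2 * diff(g$r[1:2]))
  # counting within r < L/2 only reaches part of the box volume
  expected <- 32 * (4 / 3 * pi * (max(g$r))^3) / mean(a$frame_L^3)
  expect_lt(abs(integral - expected) / expected, 0.15)
})
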