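#' Define a water isotope system
#'
#' A system is a set of identical water molecules of one isotopic
#' composition. The force-field constants are shared by all compositions;
#' the composition determines only the masses of the two covalently bound
#' sites. HDO molecules are singly deuterated: every molecule carries
#' exactly one H and one D.
#'
#' @param composition One of `"H2O"`, `"HDO"`, `"D2O"`, `"T2O"`.
#' @param n_molecules Number of molecules (>= 1).
#' @param hdo_site_order For HDO, `"HD"` puts H on the first covalent site
#'   (the site used to build the molecular frame), `"DH"` the reverse.
#' @param ff Force-field constants (for the mass table).
#' @return An object of class `isotope_system` with fields `composition`,
#'   `n_molecules`, `site_species` (length 3: "O" plus two of "H"/"D"/"T"),
#'   `site_masses` (amu) and `molar_mass` (g/mol).
#' @export
isotope_system <- function(composition = c("H2O", "HDO", "D2O", "T2O"),
                           n_molecules = 1L, hdo_site_order = c("HD", "DH"),
                           ff = qtip4pf_constants()) {
  composition <- match.arg(composition)
  hdo_site_order <- match.arg(hdo_site_order)
  sp <- switch(composition,
    H2O = c("H", "H"), D2O = c("D", "D"), T2O = c("T", "T"),
    HDO = if (hdo_site_order == "HD") c("H", "D") else c("D", "H"))
  species <- c("O", sp)
  masses <- unname(ff$masses[species])
  stopifnot(all(masses > 0), n_molecules >= 1)
  structure(list(
    composition = composition,
    n_molecules = as.integer(n_molecules),
    site_species = species,
    site_masses = masses,
    molar_mass = sum(masses)
  ), class = "isotope_system")
}

#' @export
print.isotope_system <- function(x, ...) {
  cat(sprintf("<isotope_system> %s, %d molecules, sites %s (%.4f g/mol)\n",
              x$composition, x$n_molecules,
              paste(x$site_species, collapse = "-"), x$molar_mass))
  invisible(x)
}

# Geometry of one monomer at the potential minimum, oriented in the
# xy-plane with the bisector along +x. Returns a 3 x 3 matrix (dim, site).
monomer_geometry <- function(ff = qtip4pf_constants(), r = ff$r_eq,
                             theta = ff$theta_eq) {
  h <- theta / 2
  cbind(O = c(0, 0, 0),
        X1 = r * c(cos(h), sin(h), 0),
        X2 = r * c(cos(h), -sin(h), 0))
}

#' Build an initial water box
#'
#' Places molecules at their monomer minimum geometry on a simple cubic
#' lattice with random orientations and a small positional jitter. The box
#' edge is set by the molar volume. This is an initial condition for
#' equilibration, not an equilibrated liquid.
#'
#' @param system An `isotope_system`.
#' @param v Molar volume in cm^3/mol (default 18.0, the constant-volume
#'   study condition; rho = 1.0 g/cm^3 for H2O).
#' @param L Box edge in nm; overrides `v` when given.
#' @param jitter Positional jitter amplitude (nm).
#' @param seed RNG seed.
#' @param ff Force-field constants.
#' @return List with `positions` (array 3 x 3 x n_molecules x 1) and `L`.
#' @export
water_box <- function(system, v = 18.0, L = NULL, jitter = 0.01, seed = 1,
                      ff = qtip4pf_constants()) {
  n <- system$n_molecules
  if (is.null(L)) {
    vol_nm3 <- n * v / .NA_avog * 1e21   # cm^3 -> nm^3
    L <- vol_nm3^(1 / 3)
  }
  set.seed(seed)
  ncell <- ceiling(n^(1 / 3))
  a <- L / ncell
  grid <- expand.grid(x = seq_len(ncell), y = seq_len(ncell), z = seq_len(ncell))
  grid <- grid[seq_len(n), , drop = FALSE]
  geo <- monomer_geometry(ff)
  pos <- array(0, dim = c(3, 3, n, 1))
  for (m in seq_len(n)) {
    R <- random_rotation()
    centre <- (as.numeric(grid[m, ]) - 0.5) * a +
      runif(3, -jitter, jitter)
    pos[, , m, 1] <- R %*% geo + centre
  }
  list(positions = pos, L = L)
}

# Haar-uniform random rotation matrix.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Create a ring-polymer state
#'
#' Replicates a classical configuration over `n_b` beads and samples bead
#' momenta from the ring-polymer Maxwell-Boltzmann distribution (variance
#' `m * n_b * kB * T` per bead momentum component, so centroid velocities
#' follow the classical distribution).
#'
#' @param positions Array 3 x n_site x n_mol x n_beads0 (n_beads0 = 1 to
#'   replicate a classical configuration, or already n_b beads).
#' @param system An `isotope_system`.
#' @param T Temperature (K).
#' @param L Box edge (nm); `L <= 0` means isolated (non-periodic).
#' @param n_b Number of beads.
#' @param seed RNG seed for the momenta.
#' @return Object of class `rp_state`: list(x, p, L, T, n_b, system).
#' @export
ring_polymer_state <- function(positions, system, T, L, n_b, seed = 1) {
  d <- dim(positions)
  stopifnot(length(d) == 4, d[1] == 3, d[3] == system$n_molecules, n_b >= 1)
  if (d[4] == 1 && n_b > 1) {
    positions <- array(rep(positions, n_b), dim = c(d[1:3], n_b))
  } else stopifnot(d[4] == n_b)
  nsite <- d[2]
  set.seed(seed)
  p <- array(rnorm(length(positions)), dim = dim(positions))
  for (s in seq_len(nsite)) {
    p[, s, , ] <- p[, s, , ] * sqrt(system$site_masses[s] * n_b * .kB * T)
  }
  structure(list(x = positions, p = p, L = L, T = T, n_b = as.integer(n_b),
                 system = system), class = "rp_state")
}
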