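# Hydrogen-bond detection, geometry statistics and energy.

#' Hydrogen-bond criteria
#'
#' Geometric definition: two molecules are hydrogen bonded when the OO
#' distance is below `d_OO_max` and the HOO angle (at the donor O, between
#' the O->X covalent bond and the O->O vector) is below `theta_max`.
#'
#' @param d_OO_max Maximum OO distance (nm). Default 0.35 (3.5 A).
#' @param theta_max_deg Maximum HOO angle (degrees). Default 30.
#' @return List of class `hb_criteria`.
#' @export
hb_criteria <- function(d_OO_max = 0.35, theta_max_deg = 30) {
  stopifnot(d_OO_max > 0, theta_max_deg > 0)
  structure(list(d_OO_max = d_OO_max, theta_max_deg = theta_max_deg),
            class = "hb_criteria")
}

#' Detect hydrogen bonds in one configuration
#'
#' A bond is the ordered pair (donor X site, acceptor O). For
#' path-integral configurations the detector is applied per replica.
#'
#' @param coords Array 3 x 3 x n_molecules (one bead slice; site order
#'   O, X1, X2).
#' @param L Box edge (nm); `L <= 0` for isolated clusters.
#' @param criteria An `hb_criteria`.
#' @return data.frame `donor`, `site` (1 or 2), `acceptor`, `d_oo` (nm),
#'   `theta_deg`.
#' @export
detect_hbonds <- function(coords, L = -1, criteria = hb_criteria()) {
  d <- dim(coords)
  stopifnot(length(d) == 3, d[1] == 3, d[2] == 3)
  nmol <- d[3]
  O <- coords[, 1, , drop = TRUE]
  if (is.null(dim(O))) O <- matrix(O, nrow = 3)
  dOO <- pair_dists(O, L = L)
  diag(dOO) <- Inf
  out <- list()
  ct <- cos(criteria$theta_max_deg * pi / 180)
  for (don in seq_len(nmol)) {
    acc_ok <- which(dOO[don, ] < criteria$d_OO_max)
    if (!length(acc_ok)) next
    for (s in 1:2) {
      xv <- coords[, s + 1, don] - coords[, 1, don]
      if (L > 0) xv <- xv - L * round(xv / L)
      xv <- xv / sqrt(sum(xv^2))
      for (acc in acc_ok) {
        ov <- O[, acc] - O[, don]
        if (L > 0) ov <- ov - L * round(ov / L)
        r <- sqrt(sum(ov^2))
        cth <- sum(xv * ov) / r
        if (cth > ct) {
          out[[length(out) + 1]] <- data.frame(
            donor = don, site = s, acceptor = acc, d_oo = r,
            theta_deg = acos(min(1, max(-1, cth))) * 180 / pi)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), site = integer(),
                      acceptor = integer(), d_oo = numeric(),
                      theta_deg = numeric()))
  do.call(rbind, out)
}

#' Hydrogen-bond geometry statistics over a trajectory
#'
#' Applies the geometric criterion per replica, averages the bonded-pair
#' OO distance and HOO angle within each replica, then averages over
#' replicas (and frames). For HDO the statistics are additionally split by
#' whether the donated atom is H or D.
#'
#' @param archive A `trajectory_archive` with stored frames.
#' @param criteria An `hb_criteria`.
#' @return List of class `hb_statistics`: `d_oo_mean` (A), `theta_mean`
#'   (deg), `n_hb_per_molecule`, `replica_d_oo` (per-replica means, A),
#'   `n_replicas_empty`, and for HDO a `by_species` data.frame.
#' @export
hb_geometry_stats <- function(archive, criteria = hb_criteria()) {
  fr <- archive$frames
  d <- dim(fr)
  stopifnot(length(d) == 5)
  nmol <- d[3]; nb <- d[4]; nfr <- d[5]
  sp <- archive$meta$site_species
  rep_doo <- c(); rep_th <- c(); rep_n <- c(); empty <- 0
  by_sp <- list(H = list(d = c(), th = c()), D = list(d = c(), th = c()),
                T = list(d = c(), th = c()))
  for (f in seq_len(nfr)) {
    L <- archive$frame_L[f]
    for (k in seq_len(nb)) {
      hb <- detect_hbonds(fr[, , , k, f], L, criteria)
      if (!nrow(hb)) { empty <- empty + 1; next }
      rep_doo <- c(rep_doo, mean(hb$d_oo))
      rep_th <- c(rep_th, mean(hb$theta_deg))
      rep_n <- c(rep_n, 2 * nrow(hb) / nmol)
      don_sp <- sp[hb$site + 1]
      for (ssp in unique(don_sp)) {
        selr <- don_sp == ssp
        by_sp[[ssp]]$d <- c(by_sp[[ssp]]$d, mean(hb$d_oo[selr]))
        by_sp[[ssp]]$th <- c(by_sp[[ssp]]$th, mean(hb$theta_deg[selr]))
      }
    }
  }
  if (!length(rep_doo)) stop("no hydrogen bonds found in any replica")
  bys <- do.call(rbind, lapply(names(by_sp), function(ssp) {
    if (!length(by_sp[[ssp]]$d)) return(NULL)
    data.frame(species = ssp, d_oo_A = mean(by_sp[[ssp]]$d) * 10,
               theta_deg = mean(by_sp[[ssp]]$th))
  }))
  structure(list(
    d_oo_mean = mean(rep_doo) * 10,          # nm -> Angstrom
    theta_mean = mean(rep_th),
    n_hb_per_molecule = mean(rep_n),
    replica_d_oo = rep_doo * 10,
    n_replicas_empty = empty,
    by_species = bys
  ), class = "hb_statistics")
}

#' Hydrogen-bond energy
#'
#' `E_HB = (E_pot - E_0) / n_HB`, where `E_pot` is the mean potential
#' energy per molecule of the liquid, `E_0` the mean potential energy of
#' an isolated molecule at the same temperature and bead number (both from
#' path-integral runs, so zero-point and thermal intramolecular energy
#' cancel), and `n_HB` the mean number of hydrogen bonds per molecule
#' (each donor-acceptor bond counted for both partners:
#' `n_HB = 2 bonds / molecules`).
#'
#' @param liquid A `trajectory_archive` of the liquid.
#' @param monomer A `trajectory_archive` of a single molecule at matched
#'   temperature, bead count and composition.
#' @param criteria An `hb_criteria`.
#' @param convention `"per_molecule"` (default, n_HB = 2 bonds/N) or
#'   `"per_bond"` (n_HB = bonds/N).
#' @return List of class `hb_energy`: `E_HB` (kJ/mol), `E_pot`, `E_0`,
#'   `n_hb`.
#' @export
hb_energy <- function(liquid, monomer, criteria = hb_criteria(),
                      convention = c("per_molecule", "per_bond")) {
  convention <- match.arg(convention)
  if (abs(liquid$meta$T - monomer$meta$T) > 1e-9 ||
      liquid$meta$n_b != monomer$meta$n_b ||
      liquid$meta$composition != monomer$meta$composition)
    stop("monomer run must match the liquid in T, n_b and composition")
  E_pot <- mean(liquid$estimators$U) / liquid$meta$n_molecules
  E_0 <- mean(monomer$estimators$U) / monomer$meta$n_molecules
  st <- hb_geometry_stats(liquid, criteria)
  n_hb <- st$n_hb_per_molecule
  if (convention == "per_bond") n_hb <- n_hb / 2
  if (n_hb <= 0) stop("no hydrogen bonds: E_HB undefined")
  structure(list(E_HB = (E_pot - E_0) / n_hb, E_pot = E_pot, E_0 = E_0,
                 n_hb = n_hb, convention = convention),
            class = "hb_energy")
}
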