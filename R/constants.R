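# Internal unit system: nm, ps, amu, kJ/mol, elementary charge.
# In these units 1 amu nm^2 ps^-2 = 1 kJ/mol exactly.

.kB <- 0.00831446261815324      # kJ mol^-1 K^-1
.hbar <- 0.0635077985           # kJ mol^-1 ps
.ke_coul <- 138.935458          # kJ mol^-1 nm e^-2
.NA_avog <- 6.02214076e23
.kB_MPa_nm3 <- 1.380649e-2      # MPa nm^3 K^-1 (Boltzmann constant, volume units)
.kj_nm3_to_MPa <- 1.66054
.c_cm_per_ps <- 0.0299792458    # speed of light, cm/ps (converts cycles/ps to cm^-1)

#' Physical constants used by the package
#'
#' Boltzmann constant, reduced Planck constant and Coulomb prefactor in the
#' internal unit system (nm, ps, amu, kJ/mol, e).
#'
#' @return Named list of constants.
#' @export
physical_constants <- function() {
  list(kB = .kB, hbar = .hbar, ke_coul = .ke_coul, N_A = .NA_avog,
       kB_MPa_nm3 = .kB_MPa_nm3, kJ_nm3_to_MPa = .kj_nm3_to_MPa,
       c_cm_per_ps = .c_cm_per_ps)
}

.ff_cache <- new.env(parent = emptyenv())

#' q-TIP4P/F force-field constants
#'
#' Loads the versioned q-TIP4P/F parameter file shipped with the package:
#' a quartic expansion of a Morse potential for the two covalent OH bonds,
#' a harmonic HOH bend, a Lennard-Jones site on oxygen, and point charges
#' on the two covalent hydrogen sites plus a massless M site placed on the
#' HOH bisector. The constants are isotope-independent; isotope substitution
#' enters only through the site masses.
#'
#' @param file Optional path to an alternative constants file (JSON).
#' @return An object of class `ff_constants`: a named list with elements
#'   `D_r`, `alpha_r`, `r_eq` (stretch), `k_theta`, `theta_eq` (bend, rad),
#'   `epsilon`, `sigma` (LJ), `q_H`, `q_M` (charges), `m_site_weight`,
#'   `r_c`, `eps_rf`, `shift_rf` (cutoff / reaction field) and `masses`
#'   (amu, named O/H/D/T).
#' @export
qtip4pf_constants <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.ff_cache$default)) return(.ff_cache$default)
    file <- system.file("extdata", "qtip4pf_constants.json", package = "pimdwater")
  }
  raw <- jsonlite::fromJSON(file)
  ff <- structure(list(
    D_r = raw$stretch$D_r,
    alpha_r = raw$stretch$alpha_r,
    r_eq = raw$stretch$r_eq,
    k_theta = raw$bend$k_theta,
    theta_eq = raw$bend$theta_eq_deg * pi / 180,
    epsilon = raw$lj$epsilon,
    sigma = raw$lj$sigma,
    q_H = raw$charges$q_H,
    q_M = raw$charges$q_M,
    m_site_weight = raw$m_site_weight,
    r_c = raw$cutoff$r_c,
    eps_rf = raw$cutoff$eps_rf,
    shift_rf = isTRUE(raw$cutoff$shift_rf),
    masses = unlist(raw$masses_amu),
    version = raw$version
  ), class = "ff_constants")
  stopifnot(abs(ff$q_M + 2 * ff$q_H) < 1e-10,  # molecular neutrality
            ff$r_eq > 0, ff$sigma > 0, ff$r_c > 0)
  if (is.null(file) || file == system.file("extdata", "qtip4pf_constants.json",
                                           package = "pimdwater"))
    .ff_cache$default <- ff
  ff
}

# Replace selected force-field fields (e.g. a desk-scale cutoff).
#' @rdname qtip4pf_constants
#' @param ff An `ff_constants` object.
#' @param ... Fields to override, e.g. `r_c = 0.6`.
#' @export
ff_modify <- function(ff, ...) {
  repl <- list(...)
  for (nm in names(repl)) ff[[nm]] <- repl[[nm]]
  structure(ff, class = "ff_constants")
}
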