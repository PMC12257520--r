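# Vibrational density of states and IR spectra from centroid
# time-correlation functions. In ring-polymer dynamics the centroid TCF
# approximates the Kubo-transformed quantum TCF, whose Fourier transform
# gives the spectrum.

# Autocorrelation of a vector-valued series via FFT, summed over
# components; series is a matrix (ncomp x nt). Returns lags 0..max_lag.
acf_fft <- function(series, max_lag) {
  nt <- ncol(series)
  npad <- 2^ceiling(log2(2 * nt))
  acc <- numeric(max_lag + 1)
  for (i in seq_len(nrow(series))) {
    z <- fft(c(series[i, ], rep(0, npad - nt)))
    r <- Re(fft(Mod(z)^2, inverse = TRUE)) / npad
    acc <- acc + r[1:(max_lag + 1)] / (nt - 0:max_lag)
  }
  acc
}

# Shared spectral estimator: windowed cosine transform of an ACF.
spectrum_from_acf <- function(ac, dt, zero_pad = 4, window = c("hann", "none")) {
  window <- match.arg(window)
  nlag <- length(ac)
  w <- if (window == "hann") 0.5 * (1 + cos(pi * (0:(nlag - 1)) / (nlag - 1)))
       else rep(1, nlag)
  acw <- ac * w
  npad <- zero_pad * 2^ceiling(log2(nlag))
  # one-sided Wiener-Khinchin: S(f) = dt * (2 Re FFT(acf) - acf[0])
  ext <- c(acw, rep(0, npad - nlag))
  sp <- (2 * Re(fft(ext)) - acw[1]) * dt
  freq_cm <- (0:(npad - 1)) / (npad * dt) / .c_cm_per_ps
  keep <- seq_len(floor(npad / 2))
  data.frame(freq_cm = freq_cm[keep], intensity = sp[keep])
}

#' Vibrational density of states from centroid velocities
#'
#' Mass-weighted autocorrelation of the centroid velocities (the
#' ring-polymer approximation to the Kubo-transformed velocity
#' autocorrelation), Hann-windowed and Fourier-transformed to a cm^-1
#' grid. Sampling must resolve the stretch band: a Nyquist frequency
#' below 4500 cm^-1 is refused.
#'
#' @param archive A `trajectory_archive` (or a spectral toy fixture).
#' @param species Atom selection: `"all"`, `"X"` (covalent sites only),
#'   `"O"`, `"H"`, `"D"`, `"T"`.
#' @param max_lag_frac ACF length as a fraction of the trajectory.
#' @param zero_pad Zero-padding factor.
#' @param window `"hann"` or `"none"`.
#' @return data.frame of class `spectral_density` with `freq_cm` and
#'   `intensity`; attributes record the convention metadata.
#' @export
vdos_from_velocities <- function(archive, species = "all",
                                 max_lag_frac = 0.25, zero_pad = 4,
                                 window = "hann") {
  v <- archive$velocities
  d <- dim(v)
  if (is.null(d) || length(d) != 3 || d[3] < 8)
    stop("archive holds no usable velocity series")
  dt <- archive_vel_dt(archive)
  nyq_cm <- 1 / (2 * dt) / .c_cm_per_ps
  if (nyq_cm < 4500)
    stop(sprintf(
      "Nyquist %.0f cm^-1 below 4500; stretch band unresolvable", nyq_cm))
  nsite <- length(archive$meta$site_species)
  nmol <- archive$meta$n_molecules
  sp <- rep(archive$meta$site_species, nmol)     # site fastest
  masses <- rep(archive$meta$site_masses, nmol)
  sel <- switch(species,
                all = rep(TRUE, length(sp)),
                X = sp != "O",
                sp == species)
  if (!any(sel)) stop("no atoms match the species selection")
  nt <- d[3]
  max_lag <- max(8, floor(nt * max_lag_frac))
  atoms <- which(sel)
  ac <- numeric(max_lag + 1)
  for (a in atoms) {
    ac <- ac + masses[a] * acf_fft(v[, a, , drop = TRUE], max_lag)
  }
  out <- spectrum_from_acf(ac, dt, zero_pad, window)
  out$intensity <- pmax(out$intensity, 0)
  structure(out, class = c("spectral_density", "data.frame"),
            kind = "VDOS", dt = dt, window = window, zero_pad = zero_pad,
            velocity_variance = ac[1] / sum(masses[atoms]) / 3,
            note = "centroid-velocity TCF approximates the Kubo TCF")
}

#' Infrared spectrum from the total dipole moment
#'
#' Fourier transform of the centroid (Kubo-approximating) dipole
#' autocorrelation, multiplied by the harmonic quantum-correction
#' prefactor `omega * tanh(beta hbar omega / 2)`. Peak positions are the
#' validated quantity; thermostatted ring-polymer dynamics broadens line
#' shapes.
#'
#' @param archive A `trajectory_archive` carrying a dipole series.
#' @param T Temperature (K) for the prefactor; defaults to the archive's.
#' @inheritParams vdos_from_velocities
#' @return A `spectral_density` data.frame (`freq_cm`, `intensity`).
#' @export
ir_spectrum <- function(archive, T = NULL, max_lag_frac = 0.25,
                        zero_pad = 4, window = "hann") {
  mu <- archive$dipoles
  d <- dim(mu)
  if (is.null(d) || length(d) != 2 || d[2] < 8)
    stop("archive holds no usable dipole series")
  if (is.null(T)) T <- archive$meta$T
  dt <- archive_vel_dt(archive)
  nyq_cm <- 1 / (2 * dt) / .c_cm_per_ps
  if (nyq_cm < 4500)
    stop(sprintf(
      "Nyquist %.0f cm^-1 below 4500; stretch band unresolvable", nyq_cm))
  if (all(mu == 0)) {
    nt <- d[2]
    max_lag <- max(8, floor(nt * max_lag_frac))
    out <- spectrum_from_acf(numeric(max_lag + 1), dt, zero_pad, window)
    return(structure(out, class = c("spectral_density", "data.frame"),
                     kind = "IR", dt = dt))
  }
  mu <- sweep(mu, 1, rowMeans(mu))               # remove static dipole
  nt <- d[2]
  max_lag <- max(8, floor(nt * max_lag_frac))
  ac <- acf_fft(mu, max_lag)
  out <- spectrum_from_acf(ac, dt, zero_pad, window)
  beta <- 1 / (.kB * T)
  om <- 2 * pi * out$freq_cm * .c_cm_per_ps      # rad/ps
  out$intensity <- out$intensity * om * tanh(beta * .hbar * om / 2)
  structure(out, class = c("spectral_density", "data.frame"),
            kind = "IR", dt = dt, window = window, zero_pad = zero_pad,
            prefactor = "omega * tanh(beta hbar omega / 2)",
            note = "centroid dipole TCF approximates the Kubo TCF")
}

#' Locate spectral peaks
#'
#' Local maxima above a relative intensity threshold, optionally within a
#' frequency band.
#'
#' @param sp A `spectral_density`.
#' @param band Frequency range (cm^-1) to search, e.g. `c(1800, 4500)`
#'   for the stretch band.
#' @param rel_threshold Minimum peak height relative to the band maximum.
#' @param min_separation Minimum separation between reported peaks (cm^-1).
#' @return data.frame `freq_cm`, `intensity`, strongest first.
#' @export
spectral_peaks <- function(sp, band = NULL, rel_threshold = 0.2,
                           min_separation = 200) {
  x <- sp
  if (!is.null(band)) x <- x[x$freq_cm >= band[1] & x$freq_cm <= band[2], ]
  if (nrow(x) < 3) return(data.frame(freq_cm = numeric(), intensity = numeric()))
  y <- x$intensity
  loc <- which(diff(sign(diff(y))) == -2) + 1
  loc <- loc[y[loc] >= rel_threshold * max(y)]
  if (!length(loc)) {
    loc <- which.max(y)
  }
  pk <- x[loc, c("freq_cm", "intensity")]
  pk <- pk[order(-pk$intensity), ]
  # enforce separation
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    close_by <- abs(pk$freq_cm - pk$freq_cm[i]) < min_separation
    close_by[i] <- FALSE
    keep[close_by & seq_len(nrow(pk)) > i] <- FALSE
  }
  rownames(pk) <- NULL
  pk[keep, ]
}

#' Integral of a VDOS (Parseval check helper)
#'
#' Trapezoidal integral of the spectral density over its frequency grid,
#' in the time-domain normalization of [spectrum_from_acf()].
#'
#' @param sp A `spectral_density`.
#' @return Numeric scalar.
#' @export
spectral_integral <- function(sp) {
  f <- sp$freq_cm; y <- sp$intensity
  sum(diff(f) * (head(y, -1) + tail(y, -1)) / 2)
}
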