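# Thermodynamic observables from estimator time series.

#' Block-averaged mean and standard error
#'
#' @param x Numeric series (assumed stationary).
#' @param n_blocks Number of blocks (>= 5 to report an error bar).
#' @return List `mean`, `se`, `n_blocks`. `se` is `NA` with a warning when
#'   fewer than 5 blocks are available.
#' @export
block_average <- function(x, n_blocks = 10) {
  n <- length(x)
  nb <- min(n_blocks, n)
  if (nb < 5) {
    warning("fewer than 5 blocks; refusing to report an error bar")
    return(list(mean = mean(x), se = NA_real_, n_blocks = nb))
  }
  bl <- floor(n / nb)
  bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * bl + 1):(i * bl)]),
               numeric(1))
  list(mean = mean(bm), se = sd(bm) / sqrt(nb), n_blocks = nb)
}

#' Density and molar volume from an archive
#'
#' `rho = N M / (N_A <V>)`; the molar volume is `v = M / rho`, so
#' `v * rho = M` identically. Errors come from block averaging the volume
#' series.
#'
#' @param archive A `trajectory_archive` (NPT for fluctuating volume;
#'   constant-volume archives give exact zero-variance results).
#' @param n_blocks Blocks for the error estimate.
#' @return List with `rho` (g/cm^3), `rho_se`, `v` (cm^3/mol), `v_se`,
#'   `V_mean` (nm^3).
#' @export
density_and_volume <- function(archive, n_blocks = 10) {
  V <- archive$estimators$V
  M <- archive$meta$molar_mass
  N <- archive$meta$n_molecules
  if (sd(V) == 0) {
    ba <- list(mean = V[1], se = 0, n_blocks = n_blocks)
  } else ba <- block_average(V, n_blocks)
  rho <- N * M / (.NA_avog * ba$mean * 1e-21)      # g/cm^3
  rho_se <- if (is.na(ba$se)) NA_real_ else rho * ba$se / ba$mean
  v <- M / rho
  v_se <- if (is.na(rho_se)) NA_real_ else v * rho_se / rho
  list(rho = rho, rho_se = rho_se, v = v, v_se = v_se, V_mean = ba$mean)
}

#' Isothermal compressibility from volume fluctuations
#'
#' `kappa_T = <dV^2> / (kB T <V>)`, reported in 1/GPa.
#'
#' @param archive A `trajectory_archive` with a fluctuating volume (NPT).
#' @param min_frames Below this number of volume records the estimate is
#'   flagged with a warning (wide error bar).
#' @return List `kappa_T` (1/GPa), `kappa_T_se` (block bootstrap), `n`.
#' @export
isothermal_compressibility <- function(archive, min_frames = 200) {
  V <- archive$estimators$V
  T <- archive$meta$T
  if (length(V) < min_frames)
    warning("few volume records; compressibility estimate has a wide error bar")
  kap <- function(v) var(v) * (length(v) - 1) / length(v) /
    (.kB_MPa_nm3 * T * mean(v)) * 1000   # 1/MPa -> 1/GPa
  k <- kap(V)
  # block jackknife-style spread
  nb <- min(10, floor(length(V) / 20))
  se <- NA_real_
  if (nb >= 5) {
    bl <- floor(length(V) / nb)
    ks <- vapply(seq_len(nb), function(i) kap(V[((i - 1) * bl + 1):(i * bl)]),
                 numeric(1))
    se <- sd(ks) / sqrt(nb)
  }
  list(kappa_T = k, kappa_T_se = se, n = length(V))
}

#' Heat capacity from a quartic fit of H(T) or E(T)
#'
#' Fits a fourth-order polynomial to the curve and differentiates it:
#' `C(T) = d fit / dT`, evaluated on the input grid. Enthalpy input gives
#' C_P, energy input gives C_V. Uncertainty comes from resampling the
#' input error bars. Heat capacities from finite-bead path-integral runs
#' are bead-convergence limited and should be read as trends.
#'
#' @param T Temperature grid (K), at least `order + 2` points.
#' @param y H(T) or E(T) per molecule (kJ/mol).
#' @param se Optional standard errors of `y` for resampling.
#' @param order Polynomial order (default 4).
#' @param kind `"CP"` (enthalpy input) or `"CV"` (energy input); label only.
#' @param n_resample Resampling draws for the uncertainty band.
#' @return List with `T`, `C` (J/mol/K), `C_se`, `kind`, `coefficients`.
#' @export
heat_capacity_from_curve <- function(T, y, se = NULL, order = 4,
                                     kind = c("CP", "CV"), n_resample = 200) {
  kind <- match.arg(kind)
  if (length(T) < order + 2)
    stop("need at least order + 2 temperature points")
  fit <- lm(y ~ poly(T, order, raw = TRUE))
  cf <- coef(fit)
  dcf <- cf[-1] * seq_len(order)               # derivative coefficients
  dpoly <- function(tt) drop(outer(tt, 0:(order - 1), "^") %*% dcf)
  C <- dpoly(T) * 1000                          # kJ -> J per mol per K
  C_se <- rep(NA_real_, length(T))
  if (!is.null(se)) {
    draws <- replicate(n_resample, {
      yy <- y + rnorm(length(y), sd = se)
      f <- lm(yy ~ poly(T, order, raw = TRUE))
      d <- coef(f)[-1] * seq_len(order)
      drop(outer(T, 0:(order - 1), "^") %*% d) * 1000
    })
    C_se <- apply(draws, 1, sd)
  }
  warning_msg <- paste("heat capacities from finite-bead runs are",
                       "bead-convergence limited; treat as indicative")
  message(warning_msg)
  list(T = T, C = C, C_se = C_se, kind = kind, coefficients = cf)
}

#' Locate the density maximum (or pressure minimum)
#'
#' Finds the interior extremum of rho(T) at constant P (a maximum) or of
#' P(T) at constant v (a minimum; the two routes agree where both are
#' valid) by a quadratic fit around the extremal grid point.
#'
#' @param T Temperature grid (K).
#' @param y rho(T) or P(T).
#' @param mode `"max"` for a density maximum, `"min"` for a pressure
#'   minimum.
#' @param window Number of points around the extremum used in the fit.
#' @return List with `T_extremum` (K), `se` (fit error), `ok`. When no
#'   interior extremum exists, `T_extremum` is `NA` and `note` says
#'   "none in range".
#' @export
locate_density_maximum <- function(T, y, mode = c("max", "min"), window = 5) {
  mode <- match.arg(mode)
  ord <- order(T)
  T <- T[ord]; y <- y[ord]
  i0 <- if (mode == "max") which.max(y) else which.min(y)
  if (i0 == 1 || i0 == length(T))
    return(list(T_extremum = NA_real_, se = NA_real_, ok = FALSE,
                note = "none in range"))
  half <- floor(window / 2)
  sel <- max(1, i0 - half):min(length(T), i0 + half)
  fit <- lm(y[sel] ~ T[sel] + I(T[sel]^2))
  b <- coef(fit)
  if ((mode == "max" && b[3] >= 0) || (mode == "min" && b[3] <= 0))
    return(list(T_extremum = NA_real_, se = NA_real_, ok = FALSE,
                note = "none in range"))
  Tx <- -b[2] / (2 * b[3])
  V <- suppressWarnings(vcov(fit))   # perfect fits trip summary.lm
  g <- c(0, -1 / (2 * b[3]), b[2] / (2 * b[3]^2))   # delta method
  se <- sqrt(drop(t(g) %*% V %*% g))
  if (Tx < min(T) || Tx > max(T))
    return(list(T_extremum = NA_real_, se = NA_real_, ok = FALSE,
                note = "none in range"))
  list(T_extremum = unname(Tx), se = unname(se), ok = TRUE, note = "ok")
}
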