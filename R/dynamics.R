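# Diffusion: centroid MSD, D from the Einstein relation, Arrhenius and
# mode-coupling-theory fits of D(T).

# Extract unwrapped O-centroid coordinates (3 x nmol x nframes) from an
# archive (beads averaged). The engine never wraps coordinates, so frames
# are unwrapped by construction.
o_centroids <- function(archive) {
  fr <- archive$frames
  d <- dim(fr)
  if (length(d) != 5 || d[5] < 2) stop("archive holds fewer than 2 frames")
  # mean over beads of the O site
  apply(fr[, 1, , , , drop = FALSE], c(1, 3, 5), mean)
}

#' Centroid mean-square displacement
#'
#' Multiple-time-origin MSD of the ring-polymer centroids of the O atoms.
#' Input coordinates must be unwrapped; wrapped input (jumps larger than
#' L/2 between consecutive frames) is rejected.
#'
#' @param archive A `trajectory_archive`, or an array 3 x n x n_frames of
#'   unwrapped coordinates.
#' @param max_lag Maximum lag in frames (default: a quarter of the
#'   trajectory).
#' @param dt Frame spacing (ps); taken from the archive when available.
#' @return data.frame with `t` (ps) and `msd` (nm^2).
#' @export
centroid_msd <- function(archive, max_lag = NULL, dt = NULL) {
  if (inherits(archive, "trajectory_archive")) {
    xyz <- o_centroids(archive)
    if (is.null(dt)) dt <- archive$meta$dt * archive$meta$stride_frame
    L <- archive$L
  } else {
    xyz <- archive
    if (is.null(dt)) stop("dt required for raw coordinate input")
    L <- attr(archive, "L")
  }
  d <- dim(xyz)
  nfr <- d[3]
  if (!is.null(L) && is.finite(L) && L > 0) {
    jumps <- abs(xyz[, , -1, drop = FALSE] - xyz[, , -nfr, drop = FALSE])
    if (any(jumps > L / 2))
      stop("wrapped coordinates detected (jump > L/2); unwrap before MSD")
  }
  if (is.null(max_lag)) max_lag <- max(2L, floor(nfr / 4))
  max_lag <- min(max_lag, nfr - 1L)
  msd <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    dx <- xyz[, , (1 + lag):nfr, drop = FALSE] -
      xyz[, , 1:(nfr - lag), drop = FALSE]
    msd[lag] <- mean(colSums(dx^2, dims = 1))
  }
  data.frame(t = seq_len(max_lag) * dt, msd = msd)
}

#' Diffusion coefficient from the MSD slope
#'
#' Fits `MSD(t) = 6 D t + c` over a window in the diffusive regime.
#' A log-log slope below 0.9 in the window triggers a "not diffusive"
#' warning.
#'
#' @param msd data.frame from [centroid_msd()].
#' @param window Time window `c(tmin, tmax)` (ps); default: second half.
#' @return List `D` (nm^2/ps), `D_se`, `slope_loglog`, `diffusive`.
#' @export
diffusion_from_msd <- function(msd, window = NULL) {
  if (is.null(window)) window <- c(max(msd$t) / 2, max(msd$t))
  sel <- msd$t >= window[1] & msd$t <= window[2] & msd$msd > 0
  if (sum(sel) < 3) stop("fewer than 3 MSD points in the fit window")
  fit <- lm(msd ~ t, data = msd[sel, ])
  lf <- lm(log(msd) ~ log(t), data = msd[sel, ])
  slope_ll <- unname(coef(lf)[2])
  diffusive <- slope_ll >= 0.9 && slope_ll <= 1.1
  if (!diffusive)
    warning(sprintf("not diffusive: log-log MSD slope %.2f (sub-linear or ballistic)",
                    slope_ll))
  list(D = unname(coef(fit)[2]) / 6,
       # perfect synthetic MSDs trip summary.lm's zero-residual warning
       D_se = suppressWarnings(summary(fit))$coefficients[2, 2] / 6,
       slope_loglog = slope_ll, diffusive = diffusive)
}

#' Arrhenius fit of D(T)
#'
#' Fits `D(T) = D0 exp(-E_A / kB T)` (high-temperature branch, nonlinear
#' least squares seeded by the log-linear solution).
#'
#' @param D Diffusion coefficients (A^2/ps), positive.
#' @param T Temperatures (K); at least 3 points.
#' @param T_min Only points with `T >= T_min` enter the fit (the
#'   high-temperature window; 300 K by convention). Use `-Inf` for all.
#' @return List `D0`, `D0_se` (same units as D), `E_A`, `E_A_se` (kJ/mol),
#'   `fit` (the nls object).
#' @export
arrhenius_fit <- function(D, T, T_min = 300) {
  keep <- T >= T_min
  D <- D[keep]; T <- T[keep]
  if (any(D <= 0)) { warning("dropping non-positive D"); T <- T[D > 0]; D <- D[D > 0] }
  if (length(D) < 3) stop("need at least 3 points for the Arrhenius fit")
  ll <- lm(log(D) ~ I(1 / T))
  start <- list(lnD0 = unname(coef(ll)[1]), E_A = -unname(coef(ll)[2]) * .kB)
  fit <- minpack.lm::nlsLM(D ~ exp(lnD0) * exp(-E_A / (8.31446261815324e-3 * T)),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  s <- summary(fit)$coefficients
  lnD0 <- s["lnD0", "Estimate"]; lnD0_se <- s["lnD0", "Std. Error"]
  list(D0 = exp(lnD0), D0_se = exp(lnD0) * lnD0_se,
       E_A = s["E_A", "Estimate"], E_A_se = s["E_A", "Std. Error"],
       fit = fit)
}

#' Mode-coupling-theory fit of D(T)
#'
#' Fits the MCT power law `D(T) = D1 (T - T_MCT)^gamma` on the
#' low-temperature branch, with `T_MCT` bounded below the lowest fitted
#' temperature. The parameters are sensitive to the fitting window; use
#' [fit_window_sensitivity()] to quantify that.
#'
#' @param D Diffusion coefficients (A^2/ps), positive.
#' @param T Temperatures (K); at least 4 points.
#' @param window Temperature window `c(Tlo, Thi)` (default 220-300 K,
#'   clipped to the available grid).
#' @return List `D1`, `gamma`, `T_MCT` with standard errors, `converged`,
#'   `fit`.
#' @export
mct_fit <- function(D, T, window = c(220, 300)) {
  keep <- T >= window[1] & T <= window[2] & D > 0
  D <- D[keep]; T <- T[keep]
  if (length(D) < 4) stop("need at least 4 points in the MCT window")
  Tmin <- min(T)
  start <- list(lnD1 = log(max(D)) - 2 * log(max(T) - Tmin + 50),
                gamma = 2, T_MCT = Tmin - 50)
  fit <- try(minpack.lm::nlsLM(
    D ~ exp(lnD1) * (T - T_MCT)^gamma, start = start,
    lower = c(lnD1 = -Inf, gamma = 0.1, T_MCT = -Inf),
    upper = c(lnD1 = Inf, gamma = 10, T_MCT = Tmin - 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(converged = FALSE, diagnostics = attr(fit, "condition")$message))
  s <- summary(fit)$coefficients
  lnD1 <- s["lnD1", "Estimate"]
  list(D1 = exp(lnD1), D1_se = exp(lnD1) * s["lnD1", "Std. Error"],
       gamma = s["gamma", "Estimate"], gamma_se = s["gamma", "Std. Error"],
       T_MCT = s["T_MCT", "Estimate"], T_MCT_se = s["T_MCT", "Std. Error"],
       converged = TRUE, fit = fit)
}

#' Sensitivity of fit parameters to the temperature window
#'
#' Repeats a fit with the window shifted by one grid point in each
#' direction and reports the parameter shifts.
#'
#' @param D,T As in [mct_fit()].
#' @param fit_fun `mct_fit` or `arrhenius_fit`.
#' @param window Base window.
#' @return data.frame of parameter values per window.
#' @export
fit_window_sensitivity <- function(D, T, fit_fun = mct_fit,
                                   window = c(220, 300)) {
  Ts <- sort(unique(T))
  step <- if (length(Ts) > 1) min(diff(Ts)) else 10
  wins <- list(window, window + c(step, 0), window + c(0, -step))
  out <- lapply(wins, function(w) {
    r <- try(fit_fun(D, T, w), silent = TRUE)
    if (inherits(r, "try-error") || isFALSE(r$converged))
      return(data.frame(T_lo = w[1], T_hi = w[2], converged = FALSE))
    data.frame(T_lo = w[1], T_hi = w[2], converged = TRUE,
               t(unlist(r[intersect(names(r),
                                    c("D0", "E_A", "D1", "gamma", "T_MCT"))])))
  })
  do.call(rbind, lapply(out, function(x) {
    miss <- setdiff(Reduce(union, lapply(out, names)), names(x))
    for (m in miss) x[[m]] <- NA
    x
  }))
}

#' Crossover temperature between Arrhenius and MCT branches
#'
#' Intersection of the two fitted D(T) branches, located numerically.
#'
#' @param arr Result of [arrhenius_fit()].
#' @param mct Result of [mct_fit()].
#' @param range Search range (K).
#' @return Crossover temperature (K) or `NA` if the branches do not cross.
#' @export
crossover_temperature <- function(arr, mct, range = c(200, 350)) {
  f <- function(T) arr$D0 * exp(-arr$E_A / (.kB * T)) -
    mct$D1 * pmax(T - mct$T_MCT, 1e-9)^mct$gamma
  tt <- seq(range[1], range[2], by = 0.1)
  v <- f(tt)
  sgn <- which(diff(sign(v)) != 0)
  if (!length(sgn)) return(NA_real_)
  tt[sgn[1]]
}
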