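# Structure: radial distribution functions and local order parameters.

# minimum-image displacement matrix helpers --------------------------------

# pairwise distances between two coordinate sets (3 x n), minimum image
pair_dists <- function(A, B = NULL, L) {
  same <- is.null(B)
  if (same) B <- A
  na <- ncol(A); nb <- ncol(B)
  d2 <- matrix(0, na, nb)
  for (d in 1:3) {
    dd <- outer(A[d, ], B[d, ], "-")
    if (L > 0) dd <- dd - L * round(dd / L)
    d2 <- d2 + dd^2
  }
  sqrt(d2)
}

# Extract per-bead site coordinates (3 x nmol) for one frame/bead.
frame_sites <- function(frames, frame, bead, site) frames[, site, , bead, frame]

#' Radial distribution function
#'
#' Bead-resolved RDF (same-bead pairs, the standard path-integral
#' estimator), normalized by ideal-gas shell counts. Species pairs: "OO",
#' "OX", "XX", and for HDO the OX channel resolves into "OH" and "OD".
#'
#' @param archive A `trajectory_archive` with stored frames.
#' @param pair Species pair.
#' @param bins Number of radial bins.
#' @param r_max Maximum radius (nm); must satisfy `r_max <= L/2`
#'   (default: L/2).
#' @return data.frame `r` (bin centres, nm), `g`.
#' @export
rdf <- function(archive, pair = c("OO", "OX", "XX", "OH", "OD"),
                bins = 60, r_max = NULL) {
  pair <- match.arg(pair)
  fr <- archive$frames
  d <- dim(fr)
  stopifnot(length(d) == 5)
  nmol <- d[3]; nb <- d[4]; nfr <- d[5]
  Ls <- archive$frame_L
  if (is.null(r_max)) r_max <- min(Ls) / 2
  if (r_max > min(Ls) / 2 + 1e-9) stop("r_max must be <= L/2")
  sp <- archive$meta$site_species       # length 3
  sites_for <- function(tag) {
    switch(tag,
           O = list(1L),
           X = as.list(which(sp != "O")),
           H = as.list(which(sp == "H")),
           D = as.list(which(sp == "D")),
           T = as.list(which(sp == "T")))
  }
  a_tag <- substr(pair, 1, 1); b_tag <- substr(pair, 2, 2)
  sa <- sites_for(a_tag); sb <- sites_for(b_tag)
  if (!length(sa) || !length(sb))
    stop(sprintf("species channel %s not present in %s", pair,
                 archive$meta$composition))
  edges <- seq(0, r_max, length.out = bins + 1)
  counts <- numeric(bins)
  npair_total <- 0
  for (f in seq_len(nfr)) {
    L <- Ls[f]
    for (k in seq_len(nb)) {
      for (ia in seq_along(sa)) for (ib in seq_along(sb)) {
        A <- fr[, sa[[ia]], , k, f]
        B <- fr[, sb[[ib]], , k, f]
        dm <- pair_dists(A, B, L)
        if (identical(sa[[ia]], sb[[ib]])) {
          dv <- dm[upper.tri(dm)]
          w <- 2                                   # count both directions
        } else {
          diag(dm) <- NA                           # skip intramolecular
          dv <- dm[!is.na(dm)]
          w <- 1
        }
        h <- graphics::hist(dv[dv < r_max], breaks = edges, plot = FALSE)
        counts <- counts + w * h$counts
        npair_total <- npair_total + w * length(dv)
      }
    }
  }
  V <- mean(Ls^3)
  # ideal-gas expectation: each counted pair lands in a bin with
  # probability shell/V
  shell <- 4 / 3 * pi * diff(edges^3)
  ideal <- npair_total * shell / V
  data.frame(r = (head(edges, -1) + tail(edges, -1)) / 2,
             g = counts / ideal)
}

# O coordinates used by the order parameters: ring-polymer centroids for
# quantum archives (per-replica alternative via `per_bead`).
o_frame_coords <- function(archive, per_bead = FALSE) {
  fr <- archive$frames
  d <- dim(fr)
  if (per_bead) {
    lapply(seq_len(d[5]), function(f)
      lapply(seq_len(d[4]), function(k) fr[, 1, , k, f]))
  } else {
    lapply(seq_len(d[5]), function(f)
      apply(fr[, 1, , , f, drop = FALSE], c(1, 3), mean))
  }
}

#' Tetrahedral order parameter
#'
#' `q = 1 - 3/8 sum_(j<k) (cos psi_jk + 1/3)^2` over the four nearest O
#' neighbours of each molecule; `<q> = 1` in a perfect tetrahedral network
#' (hexagonal ice) and `<q> -> 0` for randomly placed molecules. Computed
#' on ring-polymer centroids.
#'
#' @param coords O coordinates, 3 x n matrix, or a `trajectory_archive`.
#' @param L Box edge (nm) (taken from the archive if given).
#' @return For a matrix: list `q_mean`, `q` (per molecule), `skipped`.
#'   For an archive: the frame-averaged list.
#' @export
tetrahedral_q <- function(coords, L = NULL) {
  if (inherits(coords, "trajectory_archive")) {
    frames <- o_frame_coords(coords)
    Ls <- coords$frame_L
    res <- mapply(function(fc, l) tetrahedral_q(fc, l)$q_mean,
                  frames, Ls)
    return(list(q_mean = mean(res), q_frames = res, skipped = 0))
  }
  n <- ncol(coords)
  if (n < 5) stop("need at least 5 molecules (4 neighbours each)")
  dm <- pair_dists(coords, L = L)
  diag(dm) <- Inf
  qv <- rep(NA_real_, n)
  skipped <- 0
  for (i in seq_len(n)) {
    nb4 <- order(dm[i, ])[1:4]
    if (!all(is.finite(dm[i, nb4]))) { skipped <- skipped + 1; next }
    # minimum-image unit vectors to the 4 neighbours
    U <- matrix(0, 3, 4)
    for (j in 1:4) {
      v <- coords[, nb4[j]] - coords[, i]
      if (L > 0) v <- v - L * round(v / L)
      U[, j] <- v / sqrt(sum(v^2))
    }
    s <- 0
    for (j in 1:3) for (k in (j + 1):4) {
      s <- s + (sum(U[, j] * U[, k]) + 1 / 3)^2
    }
    qv[i] <- 1 - 3 / 8 * s
  }
  list(q_mean = mean(qv, na.rm = TRUE), q = qv, skipped = skipped)
}

#' First-to-second hydration shell separation
#'
#' Per-molecule distance between the first and second hydration shells,
#' implemented as the gap between the 5th- and 4th-nearest O neighbour
#' distances, averaged over molecules (approx. 0.1 nm in low-density,
#' tetrahedral environments, approx. 0 in high-density ones).
#'
#' @inheritParams tetrahedral_q
#' @return For a matrix: list `dfs_mean` (nm), `dfs` (per molecule).
#'   For an archive: the frame-averaged list.
#' @export
dfs_metric <- function(coords, L = NULL) {
  if (inherits(coords, "trajectory_archive")) {
    frames <- o_frame_coords(coords)
    Ls <- coords$frame_L
    res <- mapply(function(fc, l) dfs_metric(fc, l)$dfs_mean, frames, Ls)
    return(list(dfs_mean = mean(res), dfs_frames = res))
  }
  n <- ncol(coords)
  if (n < 6) stop("need at least 6 molecules (5 neighbours each)")
  dm <- pair_dists(coords, L = L)
  diag(dm) <- Inf
  dfs <- vapply(seq_len(n), function(i) {
    ds <- sort(dm[i, ])[1:5]
    ds[5] - ds[4]
  }, numeric(1))
  list(dfs_mean = mean(dfs), dfs = dfs)
}
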