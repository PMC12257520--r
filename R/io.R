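# Formats: extended XYZ with molecule and bead annotations, the archive
# directory container, and key-value run configuration files.

#' Write / read bead configurations as extended XYZ
#'
#' One XYZ block per frame; the comment line carries `L=<nm>` and the atom
#' lines carry species, coordinates (nm), molecule id and bead index, so a
#' bead-resolved configuration round-trips losslessly.
#'
#' @param frames Array 3 x n_site x n_mol x n_b (single frame) or
#'   3 x n_site x n_mol x n_b x n_frames.
#' @param species Per-site species labels (length n_site).
#' @param L Box edge (nm), scalar or per frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, species, L, path) {
  d <- dim(frames)
  if (length(d) == 4) { dim(frames) <- c(d, 1); d <- dim(frames) }
  stopifnot(length(d) == 5, d[1] == 3, length(species) == d[2])
  L <- rep(L, length.out = d[5])
  con <- file(path, "w")
  on.exit(close(con))
  natom <- d[2] * d[3] * d[4]
  for (f in seq_len(d[5])) {
    writeLines(as.character(natom), con)
    writeLines(sprintf("L=%.10g frame=%d", L[f], f), con)
    for (k in seq_len(d[4])) for (m in seq_len(d[3])) for (s in seq_len(d[2])) {
      writeLines(sprintf("%s %.10g %.10g %.10g %d %d", species[s],
                         frames[1, s, m, k, f], frames[2, s, m, k, f],
                         frames[3, s, m, k, f], m, k), con)
    }
  }
  invisible(path)
}

#' @rdname write_xyz
#' @param n_site,n_mol,n_b Shape of each frame (recovered from the
#'   molecule/bead columns when omitted).
#' @return For `read_xyz`: list `frames`, `species`, `L`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty xyz file")
  out_frames <- list(); Ls <- c(); species <- NULL
  i <- 1
  while (i <= length(lines)) {
    natom <- suppressWarnings(as.integer(lines[i]))
    if (is.na(natom)) stop("malformed xyz: bad atom count at line ", i)
    if (i + 1 + natom > length(lines)) stop("truncated xyz file")
    hdr <- lines[i + 1]
    Lval <- as.numeric(sub(".*L=([0-9eE.+-]+).*", "\\1", hdr))
    rows <- strsplit(lines[(i + 2):(i + 1 + natom)], "\\s+")
    tab <- do.call(rbind, rows)
    mol <- as.integer(tab[, 5]); bead <- as.integer(tab[, 6])
    nmol <- max(mol); nb <- max(bead); nsite <- natom / (nmol * nb)
    if (nsite != round(nsite)) stop("malformed xyz: inconsistent shape")
    fr <- array(0, dim = c(3, nsite, nmol, nb))
    sp <- character(nsite)
    r <- 1
    for (k in seq_len(nb)) for (m in seq_len(nmol)) for (s in seq_len(nsite)) {
      fr[, s, m, k] <- as.numeric(tab[r, 2:4])
      sp[s] <- tab[r, 1]
      r <- r + 1
    }
    out_frames[[length(out_frames) + 1]] <- fr
    Ls <- c(Ls, Lval)
    species <- sp
    i <- i + 2 + natom
  }
  d <- dim(out_frames[[1]])
  frames <- array(unlist(out_frames), dim = c(d, length(out_frames)))
  list(frames = frames, species = species, L = Ls)
}

#' Persist / load a trajectory archive
#'
#' The archive is a directory container: `meta.json` (configuration,
#' persisted verbatim), `estimators.csv`, `frames.xyz` (bead-annotated
#' extended XYZ), `velocities.csv`, `dipoles.csv`. Round-trips are
#' lossless to the printed precision.
#'
#' @param archive A `trajectory_archive`.
#' @param dir Directory to create.
#' @param stride Keep every `stride`-th frame on write.
#' @return `dir` (write) or a `trajectory_archive` (read).
#' @export
write_archive <- function(archive, dir, stride = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(archive$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(archive$estimators, file.path(dir, "estimators.csv"),
            row.names = FALSE)
  d <- dim(archive$frames)
  if (length(d) == 5 && d[5] > 0) {
    keep <- seq(1, d[5], by = stride)
    write_xyz(archive$frames[, , , , keep, drop = FALSE],
              archive$meta$site_species, archive$frame_L[keep],
              file.path(dir, "frames.xyz"))
  }
  dv <- dim(archive$velocities)
  if (length(dv) == 3 && dv[3] > 0) {
    vm <- matrix(archive$velocities, nrow = dv[3], byrow = TRUE)
    write.csv(vm, file.path(dir, "velocities.csv"), row.names = FALSE)
    write.csv(t(archive$dipoles), file.path(dir, "dipoles.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_archive
#' @export
read_archive <- function(dir) {
  metaf <- file.path(dir, "meta.json")
  if (!file.exists(metaf)) stop("not an archive directory: missing meta.json")
  meta <- jsonlite::fromJSON(metaf)
  est <- read.csv(file.path(dir, "estimators.csv"))
  fx <- file.path(dir, "frames.xyz")
  frames <- array(0, c(3, 3, 1, 1, 0)); frame_L <- numeric()
  if (file.exists(fx)) {
    xyz <- read_xyz(fx)
    frames <- xyz$frames
    frame_L <- xyz$L
  }
  vf <- file.path(dir, "velocities.csv")
  natom <- length(meta$site_species) * meta$n_molecules
  velocities <- array(0, c(3, natom, 0)); dipoles <- array(0, c(3, 0))
  if (file.exists(vf)) {
    vm <- as.matrix(read.csv(vf))
    velocities <- array(t(vm), dim = c(3, natom, nrow(vm)))
    dm <- as.matrix(read.csv(file.path(dir, "dipoles.csv")))
    dipoles <- t(dm)
    dimnames(dipoles) <- NULL
  }
  structure(list(meta = meta, estimators = est, frames = frames,
                 frame_L = frame_L, velocities = velocities,
                 dipoles = dipoles,
                 L = if (length(frame_L)) tail(frame_L, 1) else NA_real_),
            class = "trajectory_archive")
}

#' Run configuration files
#'
#' YAML key-value configs mirroring the simulation parameters
#' (composition, ensemble, T, P or v, N, n_b, dt, cutoffs, thermostat and
#' barostat settings, seeds, strides). `read_run_config` validates the
#' fields and returns the settings plus system constructors.
#'
#' @param path YAML file.
#' @return List with `system_args`, `settings` (an `integrator_settings`),
#'   `v`, and the raw `config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("composition", "ensemble", "T", "n_molecules", "n_b", "dt")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  stopifnot(cfg$composition %in% c("H2O", "HDO", "D2O", "T2O"),
            cfg$ensemble %in% c("NVT", "NPT"),
            cfg$T > 0, cfg$n_b >= 1, cfg$dt > 0)
  settings <- integrator_settings(
    n_b = as.integer(cfg$n_b), dt = cfg$dt, ensemble = cfg$ensemble,
    T = cfg$T, P = cfg$P %||% 0.1, gamma0 = cfg$gamma0 %||% 0.1,
    n_equil = as.integer(cfg$n_equil %||% 2000L),
    n_steps = as.integer(cfg$n_steps %||% 10000L),
    seed = as.integer(cfg$seed %||% 1L),
    stride_est = as.integer(cfg$stride_est %||% 10L),
    stride_frame = as.integer(cfg$stride_frame %||% 50L),
    stride_vel = as.integer(cfg$stride_vel %||% 8L))
  list(system_args = list(composition = cfg$composition,
                          n_molecules = as.integer(cfg$n_molecules)),
       settings = settings, v = cfg$v %||% 18.0, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
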