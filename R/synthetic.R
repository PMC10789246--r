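#' Ground-truth events for synthetic trajectories
#'
#' A step displacement models a conformational change: every atom of the
#' region is translated by a fixed vector from the onset frame on
#' (optionally ramped linearly over \code{ramp_frames} frames, then held).
#' A fluctuation change models destabilization without a conformational
#' change: the region's jitter amplitude switches to \code{sigma} from the
#' onset on. These are exactly the two phenomena a trajectory map and its
#' previous-step variant tell apart: a held step paints a band on the
#' fixed-reference map but only a single-column spike on the previous-step
#' map, while a fluctuation rise elevates the previous-step map over all
#' subsequent frames.
#'
#' @param region a \code{\link{region_spec}} or range string
#' @param onset_frame 1-based frame at which the event takes effect
#'   (>= 2; frame 1 is the unperturbed reference)
#' @param displacement numeric 3-vector, angstrom
#' @param ramp_frames frames over which the step ramps in linearly
#'   (0 = full step at the onset frame)
#' @param sigma new per-atom jitter standard deviation (angstrom, > 0)
#' @return object of class \code{fixture_event}
#' @name fixture_events
NULL

#' @rdname fixture_events
#' @export
event_step <- function(region, onset_frame, displacement, ramp_frames = 0L) {
  if (is.character(region)) region <- region_spec(region)
  stopifnot(length(displacement) == 3L, ramp_frames >= 0L)
  structure(list(kind = "step_displacement", region = region,
                 onset_frame = as.integer(onset_frame),
                 displacement = as.numeric(displacement),
                 ramp_frames = as.integer(ramp_frames)),
            class = "fixture_event")
}

#' @rdname fixture_events
#' @export
event_fluctuation <- function(region, onset_frame, sigma) {
  if (is.character(region)) region <- region_spec(region)
  if (sigma <= 0)
    stop("config error: fluctuation sigma must be positive", call. = FALSE)
  structure(list(kind = "fluctuation_change", region = region,
                 onset_frame = as.integer(onset_frame),
                 sigma = as.numeric(sigma)),
            class = "fixture_event")
}

#' Configuration of a synthetic backbone trajectory
#'
#' Describes an idealized, pre-aligned backbone-only trajectory with known
#' ground truth. The chain has 3.8-angstrom CA spacing and four backbone
#' atoms per residue at fixed intra-residue offsets; frame 1 is the exact
#' unperturbed geometry, and every later frame adds independent isotropic
#' Gaussian jitter of the residue's current amplitude to each atom.
#' Defaults mirror the validation conditions used throughout the test
#' suite: 30 residues, 600 frames, 0.3-angstrom base jitter.
#'
#' @param n_residues number of residues (>= 2)
#' @param n_frames number of frames (>= 2)
#' @param base_jitter_sigma per-atom, per-coordinate jitter SD (angstrom,
#'   >= 0; 0 gives a noise-free trajectory)
#' @param events list of \code{\link{fixture_events}}
#' @param seed RNG seed; identical configs are bit-identical
#' @param geometry \code{"extended_chain"} or \code{"helix"}
#' @return object of class \code{fixture_config}
#' @export
fixture_config <- function(n_residues = 30L, n_frames = 600L,
                           base_jitter_sigma = 0.3, events = list(),
                           seed = 42L,
                           geometry = c("extended_chain", "helix")) {
  geometry <- match.arg(geometry)
  n_residues <- as.integer(n_residues); n_frames <- as.integer(n_frames)
  if (n_residues < 2L || n_frames < 2L)
    stop("config error: need at least 2 residues and 2 frames", call. = FALSE)
  if (base_jitter_sigma < 0)
    stop("config error: base_jitter_sigma must be >= 0", call. = FALSE)
  ev_rows <- list()
  for (ev in events) {
    if (!inherits(ev, "fixture_event"))
      stop("config error: events must be built with event_step()/event_fluctuation()",
           call. = FALSE)
    if (ev$onset_frame < 2L || ev$onset_frame > n_frames)
      stop(sprintf("config error: onset frame %d outside 2..%d",
                   ev$onset_frame, n_frames), call. = FALSE)
    if (max(ev$region$ranges) > n_residues || min(ev$region$ranges) < 1L)
      stop(sprintf("config error: event region '%s' outside residues 1..%d",
                   ev$region$label, n_residues), call. = FALSE)
    ev_rows[[length(ev_rows) + 1L]] <-
      list(kind = ev$kind,
           rows = unlist(apply(ev$region$ranges, 1L,
                               function(r) seq(r[1], r[2]), simplify = FALSE)))
  }
  # contradictory events: two events of the same kind touching the same residue
  if (length(ev_rows) > 1L)
    for (i in seq_len(length(ev_rows) - 1L))
      for (j in seq(i + 1L, length(ev_rows)))
        if (ev_rows[[i]]$kind == ev_rows[[j]]$kind &&
            length(intersect(ev_rows[[i]]$rows, ev_rows[[j]]$rows)))
          stop("config error: overlapping events of the same kind on the same region",
               call. = FALSE)
  structure(list(n_residues = n_residues, n_frames = n_frames,
                 base_jitter_sigma = base_jitter_sigma, events = events,
                 seed = as.integer(seed), geometry = geometry),
            class = "fixture_config")
}

# base geometry: atoms x 3 matrix plus the topology tables
.fixture_base <- function(n_residues, geometry) {
  offsets <- rbind(N = c(-1.33, 0.72, 0.00),
                   CA = c(0.00, 0.00, 0.00),
                   C = c(1.26, 0.70, 0.00),
                   O = c(1.35, 1.93, 0.00))
  if (geometry == "extended_chain") {
    ca <- cbind((seq_len(n_residues) - 1L) * 3.8, 0, 0)
  } else {
    th <- (seq_len(n_residues) - 1L) * 100 * pi / 180
    ca <- cbind(2.3 * cos(th), 2.3 * sin(th),
                (seq_len(n_residues) - 1L) * 1.5)
  }
  base <- matrix(NA_real_, nrow = 4L * n_residues, ncol = 3L)
  for (i in seq_len(n_residues))
    base[4L * (i - 1L) + 1:4, ] <- sweep(offsets, 2L, ca[i, ], `+`)
  atoms <- data.frame(serial = rep(seq_len(n_residues), each = 4L),
                      name = rep(rownames(offsets), n_residues),
                      index = seq_len(4L * n_residues),
                      mass = rep(unname(.BACKBONE_MASSES[rownames(offsets)]),
                                 n_residues))
  residues <- data.frame(serial = seq_len(n_residues),
                         label = paste0("ALA", seq_len(n_residues)),
                         chain = "A", orig_resno = seq_len(n_residues),
                         stringsAsFactors = FALSE)
  list(base = base, topology = backbone_topology(residues, atoms))
}

#' Generate a synthetic backbone trajectory with known ground truth
#'
#' @param config a \code{\link{fixture_config}}
#' @return list with \code{topology}, \code{ensemble} and \code{config}
#' @examples
#' fx <- generate_fixture(fixture_config(n_residues = 5, n_frames = 20,
#'                                       base_jitter_sigma = 0))
#' compute_shift_matrix(fx$topology, fx$ensemble)
#' @export
generate_fixture <- function(config) {
  if (!inherits(config, "fixture_config"))
    config <- do.call(fixture_config, config)
  R <- config$n_residues; F_ <- config$n_frames
  g <- .fixture_base(R, config$geometry)
  A <- nrow(g$base)
  set.seed(config$seed)

  # per-residue jitter amplitude over frames
  sig <- matrix(config$base_jitter_sigma, nrow = R, ncol = F_)
  # per-residue displacement over frames
  disp <- array(0, dim = c(R, F_, 3L))
  for (ev in config$events) {
    rows <- unlist(apply(ev$region$ranges, 1L,
                         function(r) seq(r[1], r[2]), simplify = FALSE))
    frames <- seq(ev$onset_frame, F_)
    if (ev$kind == "fluctuation_change") {
      sig[rows, frames] <- ev$sigma
    } else {
      frac <- pmin(1, (frames - ev$onset_frame + 1L) / (ev$ramp_frames + 1L))
      for (k in 1:3)
        disp[rows, frames, k] <- rep(frac * ev$displacement[k],
                                     each = length(rows))
    }
  }

  coords <- array(NA_real_, dim = c(F_, A, 3L))
  res_of_atom <- rep(seq_len(R), each = 4L)
  coords[1L, , ] <- g$base
  for (f in 2L:F_) {
    x <- g$base + disp[res_of_atom, f, ]
    sig_atoms <- sig[res_of_atom, f]
    coords[f, , ] <- x + matrix(stats::rnorm(A * 3L, 0, sig_atoms), nrow = A)
  }
  list(topology = g$topology, ensemble = traj_ensemble(coords),
       config = config)
}

#' Write a fixture to disk as a topology + trajectory pair
#'
#' Writes a PDB topology plus a trajectory (AMBER NetCDF by default, or a
#' multi-frame text GRO), so the full file-based workflow can be exercised
#' end to end, together with a JSON manifest of the ground-truth events.
#'
#' @param topology a \code{\link{backbone_topology}}
#' @param ensemble a \code{\link{traj_ensemble}}
#' @param dir_path output directory (created if needed)
#' @param format trajectory format: \code{"netcdf"} (float32, ~1e-5
#'   angstrom round-trip error) or \code{"gro"} (text, 0.01 angstrom
#'   granularity)
#' @param prefix file-name prefix
#' @param config optional \code{\link{fixture_config}} recorded in the
#'   manifest
#' @return named list of written paths (\code{topology},
#'   \code{trajectory}, \code{manifest})
#' @export
write_fixture <- function(topology, ensemble, dir_path, format = c("netcdf", "gro"),
                          prefix = "fixture", config = NULL) {
  format <- match.arg(format)
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  atoms <- topology$atoms
  if (nrow(atoms) != ensemble$n_atoms)
    stop("write_fixture expects a backbone-only ensemble matching the topology",
         call. = FALSE)
  resid3 <- substr(topology$residues$label[atoms$serial], 1L, 3L)
  resno <- topology$residues$orig_resno[atoms$serial]

  top_path <- file.path(dir_path, paste0(prefix, ".pdb"))
  bio3d::write.pdb(file = top_path,
                   xyz = as.numeric(t(ensemble$coords[1L, , ])),
                   resno = resno, resid = resid3, eleno = atoms$index,
                   elety = atoms$name,
                   chain = rep("A", nrow(atoms)))

  F_ <- ensemble$n_frames
  m <- t(matrix(aperm(ensemble$coords, c(3L, 2L, 1L)), ncol = F_))
  if (format == "netcdf") {
    traj_path <- file.path(dir_path, paste0(prefix, ".nc"))
    bio3d::write.ncdf(m, trjfile = traj_path)
  } else {
    traj_path <- file.path(dir_path, paste0(prefix, ".gro"))
    write_gro(data.frame(resno = resno, resid = resid3, elety = atoms$name,
                         eleno = atoms$index, stringsAsFactors = FALSE),
              ensemble$coords, traj_path)
  }

  manifest_path <- file.path(dir_path, paste0(prefix, "_manifest.json"))
  manifest <- list(n_frames = F_, n_atoms = ensemble$n_atoms,
                   n_residues = n_residues(topology), format = format)
  if (!is.null(config))
    manifest$events <- lapply(config$events, function(ev)
      c(list(kind = ev$kind, region = ev$region$label,
             onset_frame = ev$onset_frame),
        if (ev$kind == "step_displacement")
          list(displacement = ev$displacement, ramp_frames = ev$ramp_frames)
        else list(sigma = ev$sigma)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(topology = top_path, trajectory = traj_path, manifest = manifest_path)
}
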