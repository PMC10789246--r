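#' Residue names recognized as amino acids
#'
#' Standard twenty plus common protonation/disulfide variants and MSE/SEC.
#' Non-protein residues (water, ions, ligands, nucleic acids) never enter
#' the backbone topology.
#' @keywords internal
.AA_RESID <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
               "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
               "THR", "TRP", "TYR", "VAL",
               "HID", "HIE", "HIP", "HSD", "HSE", "HSP",
               "CYX", "CYM", "ASH", "GLH", "LYN", "MSE", "SEC", "PYL")

# xyz matrix (frames x 3N, columns x1,y1,z1,x2,...) -> frames x atoms x 3
.xyz_to_array <- function(m) {
  m <- as.matrix(m)
  n_frames <- nrow(m)
  n_atoms <- ncol(m) %/% 3L
  aperm(array(t(m), dim = c(3L, n_atoms, n_frames)), c(3L, 2L, 1L))
}

# Build a backbone_topology from a flat atom table in file order.
# `atoms` needs resno, resid, elety and optionally chain; `masses` is an
# optional per-atom vector (e.g. from PRMTOP) overriding the element table.
.build_backbone_topology <- function(atoms, masses = NULL, source = "topology") {
  chain <- if (!is.null(atoms$chain)) as.character(atoms$chain) else ""
  chain[is.na(chain)] <- ""
  key <- paste(chain, atoms$resno, atoms$resid, sep = "\r")
  grp <- cumsum(c(TRUE, key[-1] != key[-length(key)]))

  first <- !duplicated(grp)
  res_tab <- data.frame(grp = grp[first],
                        resid = atoms$resid[first],
                        resno = atoms$resno[first],
                        chain = chain[first],
                        stringsAsFactors = FALSE)
  res_tab <- res_tab[res_tab$resid %in% .AA_RESID, , drop = FALSE]
  if (nrow(res_tab) == 0L)
    stop(sprintf("empty selection: no protein residues found in %s", source),
         call. = FALSE)

  keep <- grp %in% res_tab$grp & atoms$elety %in% .BACKBONE_NAMES
  bb <- data.frame(grp = grp[keep],
                   name = atoms$elety[keep],
                   index = seq_len(nrow(atoms))[keep],
                   stringsAsFactors = FALSE)
  bb$mass <- if (!is.null(masses)) masses[bb$index] else
    unname(.BACKBONE_MASSES[bb$name])

  # residues contributing no backbone heavy atom are dropped with a warning
  empty <- !(res_tab$grp %in% bb$grp)
  if (any(empty)) {
    warning(sprintf("dropping %d residue(s) with no backbone heavy atoms (%s)",
                    sum(empty),
                    paste(head(paste0(res_tab$resid[empty], res_tab$resno[empty]), 5),
                          collapse = ", ")), call. = FALSE)
    res_tab <- res_tab[!empty, , drop = FALSE]
  }

  res_tab$serial <- seq_len(nrow(res_tab))
  bb$serial <- res_tab$serial[match(bb$grp, res_tab$grp)]
  backbone_topology(
    residues = data.frame(serial = res_tab$serial,
                          label = paste0(res_tab$resid, res_tab$resno),
                          chain = res_tab$chain,
                          orig_resno = res_tab$resno,
                          stringsAsFactors = FALSE),
    atoms = bb[, c("serial", "name", "index", "mass")])
}

.read_topology_atoms <- function(top_path) {
  ext <- tolower(tools::file_ext(top_path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(top_path, verbose = FALSE)
    at <- pdb$atom
    # altLoc policy: keep the first alternate location, warn if any dropped
    alt <- at$alt
    alt[is.na(alt)] <- ""
    dup <- duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")) &
      alt != ""
    atoms <- data.frame(resno = at$resno, resid = at$resid,
                        elety = at$elety, chain = at$chain,
                        keep = !dup, stringsAsFactors = FALSE)
    if (any(dup))
      warning(sprintf("%d alternate-location atom(s) beyond the first dropped in '%s'",
                      sum(dup), top_path), call. = FALSE)
    list(atoms = atoms, masses = NULL)
  } else if (ext == "gro") {
    g <- read_gro(top_path)
    atoms <- g$atoms
    atoms$chain <- ""
    atoms$keep <- TRUE
    list(atoms = atoms, masses = NULL)
  } else if (ext %in% c("prmtop", "parm7")) {
    pt <- bio3d::read.prmtop(top_path)
    n <- length(pt$ATOM_NAME)
    ptr <- c(pt$RESIDUE_POINTER, n + 1L)
    resno <- rep(seq_along(pt$RESIDUE_LABEL), diff(ptr))
    atoms <- data.frame(resno = resno,
                        resid = pt$RESIDUE_LABEL[resno],
                        elety = trimws(pt$ATOM_NAME),
                        chain = "", keep = TRUE, stringsAsFactors = FALSE)
    list(atoms = atoms, masses = as.numeric(pt$MASS))
  } else {
    stop(sprintf("format error: unsupported topology format '.%s' for '%s' (use PDB, GRO or PRMTOP)",
                 ext, top_path), call. = FALSE)
  }
}

.read_trajectory_coords <- function(traj_path) {
  ext <- tolower(tools::file_ext(traj_path))
  if (ext == "dcd") {
    m <- bio3d::read.dcd(traj_path, verbose = FALSE)
    list(coords = .xyz_to_array(m), times = NULL)
  } else if (ext %in% c("nc", "ncdf", "netcdf")) {
    m <- bio3d::read.ncdf(traj_path, verbose = FALSE)
    tms <- tryCatch(suppressWarnings(
      bio3d::read.ncdf(traj_path, verbose = FALSE, time = TRUE)),
      error = function(e) NULL)
    if (!is.numeric(tms) || length(tms) != nrow(as.matrix(m)) ||
        any(!is.finite(tms)) || any(diff(tms) <= 0)) tms <- NULL
    list(coords = .xyz_to_array(m),
         times = if (is.null(tms)) NULL else tms / 1000)  # ps -> ns
  } else if (ext == "gro") {
    g <- read_gro(traj_path)
    tms <- g$times
    if (!is.null(tms) && (anyNA(tms) || any(diff(tms) <= 0))) tms <- NULL
    list(coords = g$coords, times = tms)
  } else if (ext == "xtc") {
    stop(sprintf("format error: XTC trajectory '%s' is not supported; convert it upstream (e.g. 'gmx trjconv' to a multi-frame .gro, or 'mdconvert'/'cpptraj' to DCD or NetCDF)",
                 traj_path), call. = FALSE)
  } else {
    stop(sprintf("format error: unsupported trajectory format '.%s' for '%s' (use DCD, NetCDF or multi-frame GRO)",
                 ext, traj_path), call. = FALSE)
  }
}

#' Load a trajectory + topology pair
#'
#' Reads a pre-aligned MD trajectory together with its topology and returns
#' the backbone topology (protein residues only, backbone heavy atoms
#' CA/C/O/N) and the full-coordinate ensemble in angstroms. Supported
#' pairs: DCD+PDB, NetCDF+PRMTOP, NetCDF+PDB and multi-frame GRO with a GRO
#' or PDB topology. GROMACS-family inputs (nm) are converted to angstroms
#' on read.
#'
#' No alignment is performed: removing whole-system rotation/translation is
#' an upstream precondition (\code{trjconv}, \code{cpptraj}). A diagnostic
#' warning is issued when the protein centroid drifts by more than
#' \code{drift_warn} angstroms over the trajectory, which usually means the
#' input was not aligned.
#'
#' @param traj_path trajectory file (.dcd, .nc, .gro)
#' @param top_path topology file (.pdb, .gro, .prmtop)
#' @param stride keep every \code{stride}-th frame, starting at the first
#' @param drift_warn centroid-drift threshold (angstrom) for the
#'   unaligned-input warning
#' @return list with elements \code{topology}
#'   (\code{\link{backbone_topology}}) and \code{ensemble}
#'   (\code{\link{traj_ensemble}})
#' @export
load_trajectory <- function(traj_path, top_path, stride = 1L, drift_warn = 10) {
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L)
    stop("stride must be a positive integer", call. = FALSE)
  for (p in c(traj_path, top_path))
    if (!file.exists(p))
      stop(sprintf("format error: cannot read '%s' (file does not exist)", p),
           call. = FALSE)

  top <- .read_topology_atoms(top_path)
  trj <- .read_trajectory_coords(traj_path)
  coords <- trj$coords

  n_top <- nrow(top$atoms)
  if (n_top != dim(coords)[2])
    stop(sprintf("atom-count mismatch: topology '%s' has %d atoms but trajectory '%s' has %d",
                 top_path, n_top, traj_path, dim(coords)[2]), call. = FALSE)

  # apply altLoc drops consistently to topology table and coordinates
  if (!all(top$atoms$keep)) {
    keep <- top$atoms$keep
    coords <- coords[, keep, , drop = FALSE]
    top$atoms <- top$atoms[keep, , drop = FALSE]
    if (!is.null(top$masses)) top$masses <- top$masses[keep]
  }

  idx <- seq(1L, dim(coords)[1], by = stride)
  coords <- coords[idx, , , drop = FALSE]
  times <- if (!is.null(trj$times)) trj$times[idx] else NULL

  topology <- .build_backbone_topology(top$atoms, top$masses,
                                       source = top_path)
  ensemble <- traj_ensemble(coords, times = times)

  cent <- apply(ensemble$coords[, topology$atoms$index, , drop = FALSE],
                c(1, 3), mean)
  drift <- sqrt(rowSums((cent - rep(cent[1, ], each = nrow(cent)))^2))
  if (max(drift) > drift_warn)
    warning(sprintf("protein centroid drifts by %.1f angstrom over the trajectory (> %.1f): input may not be aligned",
                    max(drift), drift_warn), call. = FALSE)

  list(topology = topology, ensemble = ensemble)
}
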