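#' Backbone atom masses (unified atomic mass units)
#'
#' Standard atomic weights used when the topology format carries no masses
#' (PDB, GRO). PRMTOP masses take precedence when present.
#' @keywords internal
.BACKBONE_MASSES <- c(N = 14.007, CA = 12.011, C = 12.011, O = 15.999)

#' Backbone atom names considered part of the per-residue center of mass
#' @keywords internal
.BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Construct a backbone topology
#'
#' A backbone topology records, for each protein residue, which backbone
#' heavy atoms (Calpha, C, O, N) it contributes to the trajectory and their
#' masses. Residues are numbered consecutively 1..R in chain-concatenated
#' order ("map serials"); original author numbering is kept as labels.
#'
#' @param residues data.frame with columns \code{serial} (1..R), \code{label}
#'   (e.g. \code{"GLY42"}), and optionally \code{chain}, \code{orig_resno}.
#' @param atoms data.frame with columns \code{serial} (residue map serial),
#'   \code{name} (one of CA, C, O, N), \code{index} (1-based atom index into
#'   the trajectory's atom axis), \code{mass} (u).
#' @return object of class \code{backbone_topology}
#' @export
backbone_topology <- function(residues, atoms) {
  obj <- structure(list(residues = residues, atoms = atoms),
                   class = "backbone_topology")
  validate_backbone_topology(obj)
}

#' @rdname backbone_topology
#' @param x object to validate
#' @export
validate_backbone_topology <- function(x) {
  res <- x$residues
  atm <- x$atoms
  if (nrow(res) < 1L)
    stop("backbone topology must contain at least one residue", call. = FALSE)
  if (!identical(res$serial, seq_len(nrow(res))))
    stop("residue serials must be consecutive 1..R", call. = FALSE)
  if (!all(atm$name %in% .BACKBONE_NAMES))
    stop("backbone atom names must be among CA, C, O, N", call. = FALSE)
  if (!all(atm$mass > 0))
    stop("all backbone atom masses must be positive", call. = FALSE)
  n_per <- table(factor(atm$serial, levels = res$serial))
  if (any(n_per < 1L) || any(n_per > 4L))
    stop("every residue must have between 1 and 4 backbone atoms", call. = FALSE)
  x
}

#' @export
print.backbone_topology <- function(x, ...) {
  cat(sprintf("Backbone topology: %d residues, %d backbone atoms\n",
              nrow(x$residues), nrow(x$atoms)))
  cat(sprintf("  first: %s   last: %s\n",
              x$residues$label[1], x$residues$label[nrow(x$residues)]))
  invisible(x)
}

#' Number of residues in a backbone topology
#' @param topology a \code{backbone_topology}
#' @return integer
#' @export
n_residues <- function(topology) nrow(topology$residues)

#' Construct a trajectory ensemble
#'
#' Holds the coordinates of a (pre-aligned) trajectory as a
#' frames x atoms x 3 array in angstroms, with optional per-frame times.
#'
#' @param coords numeric array, frames x atoms x 3, angstroms
#' @param times optional numeric vector of frame times (ns), strictly
#'   increasing; \code{NULL} means frame indices are used as the time axis
#' @return object of class \code{traj_ensemble}
#' @export
traj_ensemble <- function(coords, times = NULL) {
  obj <- structure(list(coords = coords, times = times,
                        n_frames = dim(coords)[1], n_atoms = dim(coords)[2]),
                   class = "traj_ensemble")
  validate_traj_ensemble(obj)
}

#' @rdname traj_ensemble
#' @param x object to validate
#' @export
validate_traj_ensemble <- function(x) {
  d <- dim(x$coords)
  if (length(d) != 3L || d[3] != 3L)
    stop("coords must be a frames x atoms x 3 array", call. = FALSE)
  if (d[1] < 2L)
    stop("an ensemble needs at least 2 frames (a reference plus one observation)",
         call. = FALSE)
  if (!all(is.finite(x$coords)))
    stop("coordinates contain non-finite values (NaN/Inf)", call. = FALSE)
  if (!is.null(x$times)) {
    if (length(x$times) != d[1])
      stop("times length must equal the number of frames", call. = FALSE)
    if (any(diff(x$times) <= 0))
      stop("frame times must be strictly increasing", call. = FALSE)
  }
  x
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d frames x %d atoms (angstrom)\n",
              x$n_frames, x$n_atoms))
  if (!is.null(x$times))
    cat(sprintf("  time: %.4g .. %.4g ns\n", x$times[1], x$times[x$n_frames]))
  invisible(x)
}

#' Construct a shift matrix
#'
#' The central container: a residues x frames matrix of shifts (angstroms),
#' with residue map serials on the rows and a 0-based frame axis on the
#' columns. \code{kind} is one of \code{"shift"} (a single trajectory's
#' map), \code{"average"} (mean of replicate maps) or \code{"difference"}
#' (signed map, A minus B).
#'
#' @param values numeric matrix, residues x frames
#' @param residue_serials integer vector of 1-based residue serials (default
#'   \code{1:nrow(values)})
#' @param frame_axis integer vector of 0-based frame indices (default
#'   \code{0:(ncol(values)-1)})
#' @param times optional numeric vector of frame times (ns)
#' @param kind one of \code{"shift"}, \code{"average"}, \code{"difference"}
#' @param meta named character vector of provenance (source files,
#'   reference mode, stride, ...)
#' @return object of class \code{shift_matrix}
#' @export
shift_matrix <- function(values, residue_serials = seq_len(nrow(values)),
                         frame_axis = seq_len(ncol(values)) - 1L,
                         times = NULL,
                         kind = c("shift", "average", "difference"),
                         meta = character()) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  obj <- structure(list(values = values,
                        residue_serials = as.integer(residue_serials),
                        frame_axis = as.integer(frame_axis),
                        times = times, kind = kind,
                        meta = meta),
                   class = "shift_matrix")
  validate_shift_matrix(obj)
}

#' @rdname shift_matrix
#' @param x object to validate
#' @export
validate_shift_matrix <- function(x) {
  v <- x$values
  if (nrow(v) != length(x$residue_serials))
    stop("row count must equal the number of residue serials", call. = FALSE)
  if (ncol(v) != length(x$frame_axis))
    stop("column count must equal the frame-axis length", call. = FALSE)
  if (x$kind %in% c("shift", "average") && any(v < 0))
    stop(sprintf("kind '%s' requires non-negative values (signed values are only valid for difference maps)",
                 x$kind), call. = FALSE)
  x
}

#' @export
print.shift_matrix <- function(x, ...) {
  cat(sprintf("Shift matrix [%s]: %d residues x %d frames\n",
              x$kind, nrow(x$values), ncol(x$values)))
  cat(sprintf("  values (angstrom): min %.4g, max %.4g\n",
              min(x$values), max(x$values)))
  if (length(x$meta))
    cat(paste0("  ", names(x$meta), " = ", x$meta, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.shift_matrix <- function(x) dim(x$values)
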