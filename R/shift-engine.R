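# Mass-weighted backbone centers of mass for all residues and frames.
# Returns an R x F x 3 array (angstrom).
.residue_coms <- function(topology, ensemble,
                          point = c("backbone_com", "ca_only")) {
  point <- match.arg(point)
  atoms <- topology$atoms
  if (point == "ca_only") {
    atoms <- atoms[atoms$name == "CA", , drop = FALSE]
    if (nrow(atoms) == 0L)
      stop("empty selection: no CA atoms in topology", call. = FALSE)
    missing <- setdiff(topology$residues$serial, atoms$serial)
    if (length(missing))
      stop(sprintf("empty selection: residue serial(s) %s have no CA atom",
                   paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  R <- n_residues(topology)
  F_ <- ensemble$n_frames
  coms <- array(NA_real_, dim = c(R, F_, 3L))
  by_res <- split(seq_len(nrow(atoms)), atoms$serial)
  for (r in seq_len(R)) {
    rows <- by_res[[as.character(r)]]
    if (is.null(rows))
      stop(sprintf("empty selection: residue serial %d has no backbone atoms", r),
           call. = FALSE)
    idx <- atoms$index[rows]
    w <- atoms$mass[rows]
    w <- w / sum(w)
    for (k in 1:3) {
      xk <- ensemble$coords[, idx, k]
      coms[r, , k] <- if (length(idx) == 1L) xk else drop(xk %*% w)
    }
  }
  coms
}

#' Backbone center of mass of one residue at one frame
#'
#' Mass-weighted mean position of the residue's backbone heavy atoms
#' (CA, C, O, N — or the CA position alone with \code{point = "ca_only"}).
#'
#' @param topology a \code{\link{backbone_topology}}
#' @param ensemble a \code{\link{traj_ensemble}}
#' @param residue 1-based residue map serial
#' @param frame 1-based frame index
#' @param point shift point: \code{"backbone_com"} (default) or
#'   \code{"ca_only"}
#' @return numeric 3-vector (angstrom)
#' @export
residue_backbone_com <- function(topology, ensemble, residue, frame,
                                 point = c("backbone_com", "ca_only")) {
  point <- match.arg(point)
  if (residue < 1L || residue > n_residues(topology))
    stop(sprintf("residue serial %d out of range 1..%d", residue,
                 n_residues(topology)), call. = FALSE)
  if (frame < 1L || frame > ensemble$n_frames)
    stop(sprintf("frame %d out of range 1..%d", frame, ensemble$n_frames),
         call. = FALSE)
  atoms <- topology$atoms
  if (point == "ca_only") atoms <- atoms[atoms$name == "CA", , drop = FALSE]
  atoms <- atoms[atoms$serial == residue, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop(sprintf("empty selection: residue serial %d has no %s atoms",
                 residue, if (point == "ca_only") "CA" else "backbone"),
         call. = FALSE)
  w <- atoms$mass / sum(atoms$mass)
  X <- matrix(ensemble$coords[frame, atoms$index, ], nrow = nrow(atoms))
  drop(w %*% X)
}

#' Compute the shift matrix of a trajectory
#'
#' For every residue \code{r} and frame \code{t} the shift is the Euclidean
#' distance between the residue's backbone center of mass at \code{t} and
#' at the reference. With \code{reference = "fixed"} the reference is one
#' fixed frame (default the first frame of the simulation), so the
#' reference column is identically zero. With \code{reference =
#' "previous"} each frame is referenced to its predecessor; such a map is
#' insensitive to stable conformational changes and shows only the
#' fluctuation amplitude (the first column is defined as zero).
#'
#' @inheritParams residue_backbone_com
#' @param reference \code{"fixed"} (default) or \code{"previous"}
#' @param ref_frame 1-based reference frame index, used only with
#'   \code{reference = "fixed"}
#' @return a \code{\link{shift_matrix}} with \code{kind = "shift"}
#' @export
compute_shift_matrix <- function(topology, ensemble,
                                 reference = c("fixed", "previous"),
                                 ref_frame = 1L,
                                 point = c("backbone_com", "ca_only")) {
  reference <- match.arg(reference)
  point <- match.arg(point)
  F_ <- ensemble$n_frames
  if (reference == "fixed") {
    ref_frame <- as.integer(ref_frame)
    if (is.na(ref_frame) || ref_frame < 1L || ref_frame > F_)
      stop(sprintf("reference frame %s out of range 1..%d", ref_frame, F_),
           call. = FALSE)
  }
  coms <- .residue_coms(topology, ensemble, point)
  R <- dim(coms)[1]
  values <- matrix(0, nrow = R, ncol = F_)
  if (reference == "fixed") {
    for (k in 1:3) {
      d <- coms[, , k] - coms[, ref_frame, k]
      values <- values + d * d
    }
  } else {
    for (k in 1:3) {
      d <- coms[, -1L, k, drop = FALSE] - coms[, -F_, k, drop = FALSE]
      values[, -1L] <- values[, -1L] + d[, , 1] * d[, , 1]
    }
  }
  values <- sqrt(values)
  meta <- c(reference_mode = if (reference == "fixed") "fixed_frame" else "previous_step",
            point = point)
  if (reference == "fixed")
    meta <- c(meta, reference_frame = as.character(ref_frame - 1L))  # 0-based
  shift_matrix(values, residue_serials = topology$residues$serial,
               times = ensemble$times, kind = "shift", meta = meta)
}

#' Calpha RMSD series of a trajectory
#'
#' Per-frame root-mean-square deviation of the CA atoms from a reference
#' frame, without superposition: the input is assumed pre-aligned, so the
#' RMSD shares the shift matrix's frame of reference and can be overlaid
#' on a trajectory map.
#'
#' @inheritParams residue_backbone_com
#' @param reference_index 1-based reference frame (default first frame)
#' @return object of class \code{rmsd_series}: list with \code{values}
#'   (angstrom, one per frame) and \code{reference_index}
#' @export
rmsd_series <- function(topology, ensemble, reference_index = 1L) {
  reference_index <- as.integer(reference_index)
  F_ <- ensemble$n_frames
  if (is.na(reference_index) || reference_index < 1L || reference_index > F_)
    stop(sprintf("reference frame %s out of range 1..%d", reference_index, F_),
         call. = FALSE)
  ca <- topology$atoms$index[topology$atoms$name == "CA"]
  if (length(ca) == 0L)
    stop("empty selection: no CA atoms in topology", call. = FALSE)
  D <- ensemble$coords[, ca, , drop = FALSE]
  ref <- D[reference_index, , , drop = TRUE]
  if (length(ca) == 1L) ref <- matrix(ref, nrow = 1L)
  sq <- (D - array(rep(ref, each = F_), dim = dim(D)))^2
  values <- sqrt(apply(sq, 1L, sum) / length(ca))
  structure(list(values = values, reference_index = reference_index,
                 times = ensemble$times),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("CA RMSD series: %d frames, max %.3f angstrom (reference frame %d)\n",
              length(x$values), max(x$values), x$reference_index))
  invisible(x)
}
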