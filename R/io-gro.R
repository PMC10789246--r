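#' Read a (possibly multi-frame) GROMACS .gro file
#'
#' GRO is a fixed-column text format: a title line (optionally carrying
#' \code{t= <time in ps>}), an atom count, one line per atom
#' (\code{\%5d\%-5s\%5s\%5d\%8.3f\%8.3f\%8.3f}), and a box line.
#' Trajectories written by \code{trjconv} are simply concatenated frames.
#' Coordinates are stored in nm and converted to angstroms on read.
#'
#' @param path path to a .gro file
#' @return list with \code{atoms} (data.frame: \code{resno}, \code{resid},
#'   \code{elety}, \code{eleno}), \code{coords} (frames x atoms x 3 array,
#'   angstrom) and \code{times} (ns, or \code{NULL} when the title lines
#'   carry no \code{t=} stamp)
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop(sprintf("format error: '%s' is too short to be a GRO file", path),
         call. = FALSE)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1L)
    stop(sprintf("format error: '%s' line 2 is not a valid GRO atom count", path),
         call. = FALSE)
  frame_len <- natoms + 3L
  n_frames <- length(lines) %/% frame_len
  if (n_frames * frame_len != length(lines))
    stop(sprintf("format error: '%s' has %d lines, not a multiple of frame length %d",
                 path, length(lines), frame_len), call. = FALSE)

  coords <- array(NA_real_, dim = c(n_frames, natoms, 3L))
  times <- rep(NA_real_, n_frames)
  atoms <- NULL
  for (f in seq_len(n_frames)) {
    off <- (f - 1L) * frame_len
    title <- lines[off + 1L]
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    if (length(tm) == 2L) times[f] <- as.numeric(tm[2]) / 1000  # ps -> ns
    rows <- lines[off + 2L + seq_len(natoms)]
    if (f == 1L) {
      atoms <- data.frame(
        resno = as.integer(substr(rows, 1L, 5L)),
        resid = trimws(substr(rows, 6L, 10L)),
        elety = trimws(substr(rows, 11L, 15L)),
        eleno = seq_len(natoms),
        stringsAsFactors = FALSE)
    }
    xyz <- matrix(as.numeric(c(substr(rows, 21L, 28L),
                               substr(rows, 29L, 36L),
                               substr(rows, 37L, 44L))),
                  ncol = 3L)
    if (anyNA(xyz))
      stop(sprintf("format error: non-numeric coordinates in '%s', frame %d",
                   path, f), call. = FALSE)
    coords[f, , ] <- xyz * 10  # nm -> angstrom
  }
  list(atoms = atoms, coords = coords,
       times = if (all(is.na(times))) NULL else times)
}

#' Write a multi-frame GRO file
#'
#' Counterpart of \code{\link{read_gro}}; used for small text fixtures.
#' Coordinates are given in angstroms and written in nm at the format's
#' native 3-decimal precision (0.01 angstrom granularity).
#'
#' @param atoms data.frame as returned by \code{read_gro}
#' @param coords frames x atoms x 3 array, angstrom
#' @param path output path
#' @param times optional frame times in ns (written as \code{t=} stamps, ps)
#' @return invisibly, \code{path}
#' @export
write_gro <- function(atoms, coords, path, times = NULL) {
  n_frames <- dim(coords)[1]
  natoms <- dim(coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    tstamp <- if (!is.null(times)) sprintf(" t= %.5f", times[f] * 1000) else ""
    writeLines(c(sprintf("frame %d%s", f - 1L, tstamp),
                 sprintf("%5d", natoms)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       atoms$resno %% 100000L, atoms$resid, atoms$elety,
                       atoms$eleno %% 100000L,
                       coords[f, , 1] / 10, coords[f, , 2] / 10,
                       coords[f, , 3] / 10), con)
    writeLines("   0.00000   0.00000   0.00000", con)
  }
  invisible(path)
}
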