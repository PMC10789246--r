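#' Specify a protein region by residue serial ranges
#'
#' A region is a union of 1-based inclusive serial ranges, written in the
#' same syntax used on the command line, e.g. \code{"30-40,171-181"} for
#' the two DNA-binding stretches of a homodimer numbered continuously.
#'
#' @param ranges either a string like \code{"30-40,171-181"} (single
#'   serials allowed: \code{"7"}), or a 2-column matrix/list of
#'   \code{c(start, end)} pairs
#' @param label display label (defaults to the range syntax)
#' @return object of class \code{region_spec}
#' @export
region_spec <- function(ranges, label = NULL) {
  if (is.character(ranges)) {
    if (is.null(label)) label <- ranges
    parts <- strsplit(gsub("\\s", "", ranges), ",", fixed = FALSE)[[1]]
    parsed <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^([0-9]+)(?:-([0-9]+))?$", p))[[1]]
      if (length(m) == 0L || !nzchar(m[1]))
        stop(sprintf("region error: cannot parse range '%s'", p), call. = FALSE)
      s <- as.integer(m[2])
      e <- if (nzchar(m[3])) as.integer(m[3]) else s
      c(s, e)
    })
    ranges <- do.call(rbind, parsed)
  } else if (is.list(ranges)) {
    ranges <- do.call(rbind, lapply(ranges, as.integer))
  } else {
    ranges <- matrix(as.integer(ranges), ncol = 2L)
  }
  colnames(ranges) <- c("start", "end")
  if (any(ranges[, 1] > ranges[, 2]))
    stop("region error: range start must not exceed end", call. = FALSE)
  if (is.null(label))
    label <- paste(ifelse(ranges[, 1] == ranges[, 2], ranges[, 1],
                          paste0(ranges[, 1], "-", ranges[, 2])),
                   collapse = ",")
  structure(list(ranges = ranges, label = label), class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("Region '%s' (%d residues)\n", x$label,
              sum(x$ranges[, 2] - x$ranges[, 1] + 1L)))
  invisible(x)
}

# Row indices of a map selected by a region (validated against serials)
.region_rows <- function(map, region) {
  rows <- integer()
  for (i in seq_len(nrow(region$ranges))) {
    s <- region$ranges[i, 1]; e <- region$ranges[i, 2]
    hit <- which(map$residue_serials >= s & map$residue_serials <= e)
    if (length(hit) != e - s + 1L)
      stop(sprintf("region error: range %d-%d not fully contained in the map's serials (%d..%d)",
                   s, e, min(map$residue_serials), max(map$residue_serials)),
           call. = FALSE)
    rows <- c(rows, hit)
  }
  sort(unique(rows))
}

.check_same_shape <- function(a, b, what = "maps") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("dimension error: %s have shapes %dx%d and %dx%d",
                 what, nrow(a$values), ncol(a$values),
                 nrow(b$values), ncol(b$values)), call. = FALSE)
  invisible(TRUE)
}

#' Average two or three trajectory maps
#'
#' Element-wise mean of replicate maps — e.g. the average course of a
#' duplicate or triplicate simulation. Inputs must share the same shape
#' and be of kind \code{shift} or \code{average}.
#'
#' @param maps list of 2 or 3 \code{\link{shift_matrix}} objects
#' @return a \code{\link{shift_matrix}} with \code{kind = "average"}
#' @export
average_maps <- function(maps) {
  if (inherits(maps, "shift_matrix")) maps <- list(maps)
  if (length(maps) < 2L || length(maps) > 3L)
    stop(sprintf("arity error: average_maps takes 2 or 3 maps, got %d",
                 length(maps)), call. = FALSE)
  for (m in maps) {
    if (!m$kind %in% c("shift", "average"))
      stop(sprintf("cannot average maps of kind '%s'", m$kind), call. = FALSE)
    .check_same_shape(maps[[1]], m)
  }
  values <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  shift_matrix(values, residue_serials = maps[[1]]$residue_serials,
               frame_axis = maps[[1]]$frame_axis, times = maps[[1]]$times,
               kind = "average",
               meta = c(n_sources = as.character(length(maps))))
}

#' Difference of two trajectory maps
#'
#' Element-wise \code{a - b}. Shifts stronger in \code{a} yield positive
#' values, shifts stronger in \code{b} negative ones; similar shifts stay
#' near zero. Operands may themselves be replicate averages, giving e.g.
#' the four-simulation comparison (avg(A, A') - avg(B, B')) =
#' (A + A' - B - B')/2.
#'
#' @param a,b \code{\link{shift_matrix}} objects of kind \code{shift} or
#'   \code{average}, same shape
#' @return a \code{\link{shift_matrix}} with \code{kind = "difference"}
#' @export
difference_map <- function(a, b) {
  for (m in list(a, b))
    if (!m$kind %in% c("shift", "average"))
      stop(sprintf("cannot difference a map of kind '%s'", m$kind),
           call. = FALSE)
  .check_same_shape(a, b)
  shift_matrix(a$values - b$values, residue_serials = a$residue_serials,
               frame_axis = a$frame_axis, times = a$times,
               kind = "difference")
}

#' Extract a region's shift graph from a map
#'
#' The per-frame unweighted mean shift over all residues of a region — a
#' slice of the trajectory map through the y axis, with the colour scale
#' promoted to the y axis of a 2-D graph. Works on difference maps, where
#' the output is signed.
#'
#' @param map a \code{\link{shift_matrix}}
#' @param region a \code{\link{region_spec}} (or a range string, which is
#'   parsed)
#' @return object of class \code{shift_series}: \code{values} (angstrom,
#'   one per frame), \code{frame_axis}, \code{times}, \code{region},
#'   \code{kind}, and optional \code{smoothed}/\code{window} once
#'   \code{\link{moving_average}} has been applied
#' @export
region_shift_series <- function(map, region) {
  if (is.character(region)) region <- region_spec(region)
  rows <- .region_rows(map, region)
  values <- colMeans(map$values[rows, , drop = FALSE])
  structure(list(values = values, frame_axis = map$frame_axis,
                 times = map$times, region = region, kind = map$kind,
                 smoothed = NULL, window = NULL),
            class = "shift_series")
}

#' @export
print.shift_series <- function(x, ...) {
  cat(sprintf("Shift series for region '%s': %d frames, mean %.3f angstrom%s\n",
              x$region$label, length(x$values), mean(x$values),
              if (!is.null(x$window))
                sprintf(" (smoothed, window %d)", x$window) else ""))
  invisible(x)
}

#' Centered moving average of a shift series
#'
#' Smooths a shift series with a centered window; at the edges the window
#' is truncated symmetrically to the available neighbours, so the output
#' has the same length as the input and a window of 1 is the identity.
#' The smoothed curve is stored alongside the raw values (the raw series
#' is never overwritten).
#'
#' @param series a \code{\link{shift_series}}, or a bare numeric vector
#' @param window positive integer window length (frames)
#' @return the series with \code{smoothed} and \code{window} filled in;
#'   for a bare numeric input, the smoothed numeric vector
#' @export
moving_average <- function(series, window) {
  v <- if (inherits(series, "shift_series")) series$values else as.numeric(series)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window > length(v))
    stop(sprintf("parameter error: window must be in 1..%d, got %s",
                 length(v), window), call. = FALSE)
  # centered window; for even windows the extra point goes to the right
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (!inherits(series, "shift_series")) return(sm)
  series$smoothed <- sm
  series$window <- window
  series
}
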