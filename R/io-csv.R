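#' Write a shift matrix to the CSV interchange format
#'
#' The two-step workflow stores shift matrices between preprocessing and
#' map-making as plain CSV: optional \code{# key=value} comment lines
#' (kind, reference mode, source, stride, ...), a header row
#' \code{residue,f0,f1,...}, then one row per residue — the 1-based map
#' serial followed by the shift values printed with six decimal places.
#'
#' @param matrix a \code{\link{shift_matrix}}
#' @param out_path output path
#' @return invisibly, \code{out_path}
#' @seealso \code{\link{read_shift_csv}}
#' @export
write_shift_csv <- function(matrix, out_path) {
  validate_shift_matrix(matrix)
  con <- tryCatch(file(out_path, "w"),
                  error = function(e)
                    stop(sprintf("I/O error: cannot write '%s'", out_path),
                         call. = FALSE))
  on.exit(close(con))
  meta <- matrix$meta
  meta <- meta[names(meta) != "kind"]
  writeLines(sprintf("# kind=%s", matrix$kind), con)
  if (length(meta))
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  if (!is.null(matrix$times))
    writeLines(sprintf("# times=%s",
                       paste(format(matrix$times, digits = 10), collapse = ";")),
               con)
  writeLines(paste(c("residue", paste0("f", matrix$frame_axis)),
                   collapse = ","), con)
  vals <- apply(matrix$values, 1L,
                function(r) paste(sprintf("%.6f", r), collapse = ","))
  writeLines(paste(matrix$residue_serials, vals, sep = ","), con)
  invisible(out_path)
}

#' Read a shift matrix from the CSV interchange format
#'
#' Inverse of \code{\link{write_shift_csv}}. Malformed rows raise a parse
#' error naming the offending data row; a matrix declared
#' \code{kind=shift} or \code{kind=average} containing negative values is
#' rejected as an invariant violation.
#'
#' @param in_path path to a shift-matrix CSV
#' @return a \code{\link{shift_matrix}}
#' @export
read_shift_csv <- function(in_path) {
  if (!file.exists(in_path))
    stop(sprintf("I/O error: cannot read '%s' (file does not exist)", in_path),
         call. = FALSE)
  lines <- readLines(in_path, warn = FALSE)
  is_comment <- grepl("^#", lines)
  meta <- character()
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^#\\s*([^=]+?)\\s*=\\s*(.*)$", cl))[[1]]
    if (length(m) == 3L) meta[m[2]] <- m[3]
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 2L)
    stop(sprintf("parse error: '%s' has no data rows", in_path), call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (header[1] != "residue" || !all(grepl("^f[0-9]+$", header[-1])))
    stop(sprintf("parse error: '%s' header must be 'residue,f0,f1,...'", in_path),
         call. = FALSE)
  frame_axis <- as.integer(sub("^f", "", header[-1]))
  n_col <- length(header)

  rows <- strsplit(body[-1], ",", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != n_col))
    stop(sprintf("parse error in '%s': data row %d has %d fields, expected %d",
                 in_path, which(lens != n_col)[1], lens[lens != n_col][1], n_col),
         call. = FALSE)
  flat <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(flat)) {
    bad <- which(vapply(rows, function(r) anyNA(suppressWarnings(as.numeric(r))),
                        logical(1)))[1]
    stop(sprintf("parse error in '%s': non-numeric field in data row %d",
                 in_path, bad), call. = FALSE)
  }
  m <- matrix(flat, ncol = n_col, byrow = TRUE)
  serials <- as.integer(m[, 1])
  values <- m[, -1, drop = FALSE]

  kind <- if ("kind" %in% names(meta)) meta[["kind"]] else "shift"
  times <- NULL
  if ("times" %in% names(meta)) {
    times <- as.numeric(strsplit(meta[["times"]], ";", fixed = TRUE)[[1]])
    if (length(times) != ncol(values)) times <- NULL
  }
  meta <- meta[!names(meta) %in% c("kind", "times")]
  shift_matrix(values, residue_serials = serials, frame_axis = frame_axis,
               times = times, kind = kind, meta = meta)
}

#' Write a shift series as two-column CSV
#'
#' Frame/value pairs with the same comment-header conventions as the
#' matrix CSV (region, window, kind).
#'
#' @param series a \code{\link{shift_series}}
#' @param out_path output path
#' @param smoothed also write the smoothed companion column when present
#' @return invisibly, \code{out_path}
#' @export
write_series_csv <- function(series, out_path, smoothed = TRUE) {
  con <- tryCatch(file(out_path, "w"),
                  error = function(e)
                    stop(sprintf("I/O error: cannot write '%s'", out_path),
                         call. = FALSE))
  on.exit(close(con))
  writeLines(sprintf("# region=%s", series$region$label), con)
  if (!is.null(series$smoothed) && smoothed)
    writeLines(sprintf("# window=%d", series$window), con)
  has_sm <- !is.null(series$smoothed) && smoothed
  writeLines(paste(c("frame", "value", if (has_sm) "smoothed"),
                   collapse = ","), con)
  cols <- cbind(sprintf("%d", series$frame_axis),
                sprintf("%.6f", series$values))
  if (has_sm) cols <- cbind(cols, sprintf("%.6f", series$smoothed))
  writeLines(apply(cols, 1L, paste, collapse = ","), con)
  invisible(out_path)
}
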