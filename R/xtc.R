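# Frame-level scanner for Gromacs .xtc trajectories.
#
# .xtc is XDR-encoded (big-endian, 4-byte aligned). Each frame starts with a
# header of four 32-bit words: magic (1995), atom count, step number, time
# (float, ps), followed by the 3x3 box (nine floats) and the coordinate
# block. Coordinates are stored uncompressed (3 floats per atom) for systems
# of at most 9 atoms, and otherwise as a compressed block whose layout
# advertises its own byte length, so frames can be counted without ever
# decompressing coordinates.

XTC_MAGIC <- 1995L

#' Scan a Gromacs .xtc trajectory for frame and particle counts
#'
#' Walks the XDR frame structure reading headers only: per frame the magic
#' number, atom count, step and time, then skips the box and the coordinate
#' block (for more than 9 atoms, by reading the compressed-block layout —
#' second atom count, precision, min/max integer bounds, small-index and the
#' byte count — and advancing by the byte count rounded up to a multiple of
#' 4). Coordinates are never decompressed.
#'
#' @param x a raw vector or a path to an .xtc file.
#' @return an object of class `xtc_summary`: list with `n_atoms`, `n_frames`
#'   (complete frames only), `first_time_ps`, `last_time_ps` (`NA` when no
#'   complete frame) and `truncated` (`TRUE` when a trailing partial frame
#'   was encountered).
#' @section Errors: a file whose first frame does not start with the XTC
#'   magic number 1995 is rejected (`bad magic`: the file is not an .xtc);
#'   a later frame with a different atom count raises an inconsistency
#'   error. A partial trailing frame is not an error: the scan stops and
#'   `truncated` is set.
#' @examples
#' fx <- make_xtc(n_atoms = 5, n_frames = 3, seed = 1)
#' scan_xtc(fx$bytes)$n_frames
#' @export
scan_xtc <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- readBin(x, "raw", n = file.size(x))
  }
  stopifnot(is.raw(x))
  n <- length(x)
  pos <- 1L

  # readers return NULL on exhaustion instead of erroring
  take_int <- function() {
    if (pos + 3L > n) return(NULL)
    v <- readBin(x[pos:(pos + 3L)], "integer", size = 4L, endian = "big")
    pos <<- pos + 4L
    v
  }
  take_float <- function() {
    if (pos + 3L > n) return(NULL)
    v <- readBin(x[pos:(pos + 3L)], "numeric", size = 4L, endian = "big")
    pos <<- pos + 4L
    v
  }
  skip <- function(nbytes) {
    if (pos + nbytes - 1L > n) return(NULL)
    pos <<- pos + as.integer(nbytes)
    TRUE
  }

  n_atoms <- NA_integer_
  n_frames <- 0L
  first_time <- NA_real_
  last_time <- NA_real_
  truncated <- FALSE

  repeat {
    if (pos > n) break  # clean end of stream
    frame_start <- pos

    magic <- take_int()
    if (is.null(magic)) { truncated <- TRUE; break }
    if (magic != XTC_MAGIC) {
      if (n_frames == 0L && frame_start == 1L) {
        stop("xtc: bad magic number in first frame (", magic,
             "); not an XTC file", call. = FALSE)
      }
      # mid-stream garbage: treat like a corrupt/partial tail
      truncated <- TRUE
      break
    }

    natoms <- take_int()
    step <- take_int()
    time <- take_float()
    if (is.null(natoms) || is.null(step) || is.null(time)) { truncated <- TRUE; break }
    if (is.na(n_atoms)) {
      if (natoms < 1L) stop("xtc: non-positive atom count", call. = FALSE)
      n_atoms <- natoms
    } else if (natoms != n_atoms) {
      stop(sprintf("xtc: inconsistent atom count (frame %d has %d, first frame %d)",
                   n_frames + 1L, natoms, n_atoms), call. = FALSE)
    }

    if (is.null(skip(9L * 4L))) { truncated <- TRUE; break }  # box

    if (natoms <= 9L) {
      if (is.null(skip(3L * natoms * 4L))) { truncated <- TRUE; break }
    } else {
      lsize <- take_int()                       # second atom count
      prec <- take_float()                      # precision
      ok <- !is.null(lsize) && !is.null(prec) &&
        !is.null(skip(3L * 4L)) &&              # min ints
        !is.null(skip(3L * 4L))                 # max ints
      smallidx <- if (ok) take_int() else NULL
      nbytes <- if (!is.null(smallidx)) take_int() else NULL
      if (is.null(nbytes)) { truncated <- TRUE; break }
      padded <- 4L * ((nbytes + 3L) %/% 4L)     # XDR 4-byte alignment
      if (is.null(skip(padded))) { truncated <- TRUE; break }
    }

    n_frames <- n_frames + 1L
    if (n_frames == 1L) first_time <- time
    last_time <- time
  }

  structure(
    list(
      n_atoms = n_atoms,
      n_frames = n_frames,
      first_time_ps = first_time,
      last_time_ps = last_time,
      truncated = truncated
    ),
    class = "xtc_summary"
  )
}

#' @export
print.xtc_summary <- function(x, ...) {
  cat("XTC trajectory scan\n")
  cat("  atoms:  ", x$n_atoms, "\n")
  cat("  frames: ", x$n_frames,
      if (isTRUE(x$truncated)) " (+ trailing partial frame)" else "", "\n", sep = "")
  if (!is.na(x$first_time_ps)) {
    cat("  time:   ", x$first_time_ps, " .. ", x$last_time_ps, " ps\n", sep = "")
  }
  invisible(x)
}
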