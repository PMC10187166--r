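# Parser for the Gromacs .gro coordinate format.
#
# .gro is a fixed-column text format: a free-text title line, the declared
# atom count, one line per atom, and a final box line. Atom lines use
# 5-character fields for residue number, residue name, atom name and atom
# number, followed by three 8-character position fields (nm) and, optionally,
# three 8-character velocity fields (nm/ps).

#' Parse a Gromacs .gro structure file
#'
#' Reads the fixed-column .gro coordinate format: title, declared particle
#' count, per-atom lines (columns 1-5 residue number, 6-10 residue name,
#' 11-15 atom name, 16-20 atom number, then three 8-wide position fields and
#' optionally three 8-wide velocity fields) and the box line.
#'
#' Residue and atom numbers wrap above 99,999 in large systems; they are
#' accepted as-is and never used for counting. The particle count is always
#' the declared count checked against the number of atom lines.
#'
#' @param x a file path, a single string containing the file, or a character
#'   vector of lines. LF and CRLF are both accepted.
#' @return an object of class `gro_structure`: a list with `title`,
#'   `declared_atom_count`, `atoms` (a data.frame with columns
#'   `residue_number`, `residue_name`, `atom_name`, `atom_number`, `x`, `y`,
#'   `z` and, when present, `vx`, `vy`, `vz`), `box` (3 or 9 numerics, nm)
#'   and `has_velocities`.
#' @examples
#' gro <- parse_gro(c(
#'   "Water", "3",
#'   "    1SOL     OW    1   0.230   0.628   0.113",
#'   "    1SOL    HW1    2   0.137   0.626   0.150",
#'   "    1SOL    HW2    3   0.231   0.589   0.021",
#'   "   1.86206   1.86206   1.86206"))
#' gro$declared_atom_count
#' @seealso [summarize_composition()] to profile the molecular system,
#'   [make_gro()] to generate synthetic files.
#' @export
parse_gro <- function(x) {
  lines <- read_text_lines(x)
  # drop trailing blank lines only; internal blanks are malformed atom lines
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 3L) {
    stop("gro: need at least title, atom count and box lines", call. = FALSE)
  }
  title <- lines[1L]
  declared <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(declared) || declared < 0L) {
    stop("gro: malformed atom count line (line 2): ", sQuote(trimws(lines[2L])),
         call. = FALSE)
  }
  n_body <- length(lines) - 3L
  if (n_body != declared) {
    stop(sprintf(
      "gro: declared atom count (%d) does not match number of atom lines (%d)",
      declared, n_body), call. = FALSE)
  }
  atom_lines <- if (declared > 0L) lines[seq.int(3L, 2L + declared)] else character(0)
  box_line <- lines[length(lines)]

  box <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1L]]))
  if (anyNA(box) || !(length(box) %in% c(3L, 9L))) {
    stop("gro: malformed box line, expected 3 or 9 numeric fields: ",
         sQuote(trimws(box_line)), call. = FALSE)
  }

  atoms <- parse_gro_atom_lines(atom_lines, first_line_number = 3L)

  structure(
    list(
      title = title,
      declared_atom_count = declared,
      atoms = atoms,
      box = box,
      has_velocities = isTRUE(attr(atoms, "has_velocities"))
    ),
    class = "gro_structure"
  )
}

#' @noRd
parse_gro_atom_lines <- function(atom_lines, first_line_number) {
  n <- length(atom_lines)
  empty <- data.frame(
    residue_number = integer(0), residue_name = character(0),
    atom_name = character(0), atom_number = integer(0),
    x = numeric(0), y = numeric(0), z = numeric(0),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    attr(empty, "has_velocities") <- FALSE
    return(empty)
  }

  field <- function(from, to) substr(atom_lines, from, to)
  num <- function(s) suppressWarnings(as.numeric(s))

  residue_number <- num(field(1L, 5L))
  residue_name <- trimws(field(6L, 10L))
  atom_name <- trimws(field(11L, 15L))
  atom_number <- num(field(16L, 20L))
  x <- num(field(21L, 28L))
  y <- num(field(29L, 36L))
  z <- num(field(37L, 44L))

  bad <- is.na(residue_number) | is.na(atom_number) |
    is.na(x) | is.na(y) | is.na(z) |
    !nzchar(residue_name) | !nzchar(atom_name) |
    !is.finite(x) | !is.finite(y) | !is.finite(z)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("gro: malformed atom line %d: %s",
                 first_line_number + i - 1L, sQuote(atom_lines[i])),
         call. = FALSE)
  }

  atoms <- data.frame(
    residue_number = as.integer(residue_number),
    residue_name = residue_name,
    atom_name = atom_name,
    atom_number = as.integer(atom_number),
    x = x, y = y, z = z,
    stringsAsFactors = FALSE
  )

  # lines longer than 44 + 24 characters carry the three velocity fields
  has_vel <- all(nchar(atom_lines) >= 68L)
  if (has_vel) {
    vx <- num(field(45L, 52L)); vy <- num(field(53L, 60L)); vz <- num(field(61L, 68L))
    if (anyNA(vx) || anyNA(vy) || anyNA(vz)) {
      i <- which(is.na(vx) | is.na(vy) | is.na(vz))[1L]
      stop(sprintf("gro: malformed velocity fields on atom line %d",
                   first_line_number + i - 1L), call. = FALSE)
    }
    atoms$vx <- vx; atoms$vy <- vy; atoms$vz <- vz
  }
  attr(atoms, "has_velocities") <- has_vel
  atoms
}

#' @export
print.gro_structure <- function(x, ...) {
  cat("Gromacs structure (.gro)\n")
  cat("  title:    ", x$title, "\n", sep = "")
  cat("  particles:", x$declared_atom_count, "\n")
  cat("  box (nm): ", paste(format(x$box, digits = 6), collapse = " "), "\n", sep = "")
  cat("  velocities:", if (x$has_velocities) "yes" else "no", "\n")
  invisible(x)
}
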