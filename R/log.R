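# Light-weight extraction from Gromacs .log run logs.

#' Extract run provenance from a Gromacs .log file
#'
#' Finds the Gromacs version from the first banner line (either the modern
#' `GROMACS version:  2021.4` form or the classic `:-)  GROMACS - gmx mdrun,
#' 2019.6  (-:` banner) and the invocation from the `Command line:` block
#' (the command is on the following non-empty line).
#'
#' @param x file path, single string, or character vector of lines.
#' @return an object of class `log_summary`: list with `gromacs_version` and
#'   `command_line`, each `NA` when not found (never empty strings).
#' @export
parse_log <- function(x) {
  lines <- read_text_lines(x)

  version <- NA_character_
  m <- regexpr("GROMACS version:\\s*(\\S+)", lines, perl = TRUE)
  hit <- which(m > 0L)
  if (length(hit) > 0L) {
    i <- hit[1L]
    version <- sub(".*GROMACS version:\\s*(\\S+).*", "\\1", lines[i], perl = TRUE)
  } else {
    # ":-)  GROMACS - gmx mdrun, 2021.4  (-:" style banner
    b <- grep("^\\s*:-\\)\\s+GROMACS", lines)
    if (length(b) > 0L) {
      cand <- sub("\\s*\\(-:\\s*$", "", lines[b[1L]])
      cand <- sub(".*,\\s*", "", cand)
      cand <- trimws(cand)
      if (nzchar(cand)) version <- cand
    }
  }
  version <- sub("^VERSION\\s+", "", version)  # very old banners

  command <- NA_character_
  c_idx <- grep("^\\s*Command line:\\s*$", lines)
  if (length(c_idx) > 0L) {
    j <- c_idx[1L] + 1L
    while (j <= length(lines) && !nzchar(trimws(lines[j]))) j <- j + 1L
    if (j <= length(lines) && nzchar(trimws(lines[j]))) command <- trimws(lines[j])
  }

  if (!is.na(version) && !nzchar(version)) version <- NA_character_

  structure(
    list(gromacs_version = version, command_line = command),
    class = "log_summary"
  )
}

#' @export
print.log_summary <- function(x, ...) {
  cat("Gromacs log summary\n")
  cat("  version:     ", if (is.na(x$gromacs_version)) "<absent>" else x$gromacs_version, "\n", sep = "")
  cat("  command line:", if (is.na(x$command_line)) " <absent>" else paste0(" ", x$command_line), "\n", sep = "")
  invisible(x)
}
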