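# Parser and summariser for Gromacs .mdp run-parameter files.

#' Parse a Gromacs .mdp parameter file
#'
#' .mdp files are `key = value` text. Comments run from `;` to end of line
#' and are stripped; blank lines are skipped; each remaining line is split on
#' its first `=`. Keys are normalised to lowercase with `-` mapped to `_`
#' (Gromacs treats `ref-t` and `ref_t`, `Tcoupl` and `tcoupl`, as the same
#' parameter); values are stored verbatim after trimming. Duplicate keys
#' resolve last-wins, matching the Gromacs preprocessor.
#'
#' @param x file path, single string, or character vector of lines.
#' @return an object of class `mdp_parameters`: list with `entries` (named
#'   character vector, insertion-ordered), `source_line_count`, and
#'   `warnings` (character vector; lines without `=` are recorded here, never
#'   fatal).
#' @examples
#' p <- parse_mdp("dt = 0.002 ; 2 fs\nnsteps = 500000")
#' p$entries[["dt"]]
#' @export
parse_mdp <- function(x) {
  lines <- read_text_lines(x)
  n_source <- length(lines)
  warnings <- character(0)

  lines <- sub(";.*$", "", lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]

  entries <- character(0)
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0L) {
      warnings <- c(warnings, paste0("line without '=': ", sQuote(trimws(ln))))
      next
    }
    key <- normalize_mdp_key(substr(ln, 1L, eq - 1L))
    if (!nzchar(key)) {
      warnings <- c(warnings, paste0("empty key: ", sQuote(trimws(ln))))
      next
    }
    value <- trimws(substr(ln, eq + 1L, nchar(ln)))
    entries[[key]] <- value  # last occurrence wins, order of first insertion kept
  }

  structure(
    list(entries = entries, source_line_count = n_source, warnings = warnings),
    class = "mdp_parameters"
  )
}

#' @noRd
normalize_mdp_key <- function(key) {
  gsub("-", "_", tolower(trimws(key)), fixed = TRUE)
}

#' Serialize parsed .mdp parameters back to text
#'
#' Renders `key = value` lines in entry order. `parse_mdp()` of the result
#' reproduces the entries exactly (idempotence under re-serialization).
#'
#' @param params an `mdp_parameters` object.
#' @return a single string.
#' @export
format_mdp <- function(params) {
  stopifnot(inherits(params, "mdp_parameters"))
  paste0(paste(names(params$entries), "=", params$entries, collapse = "\n"), "\n")
}

#' Summarise the simulation set-up described by an .mdp file
#'
#' Extracts the parameters that characterise an MD set-up: integrator, time
#' step, number of steps, first reference temperature, and the
#' thermostat/barostat choices (normalised onto the documented Gromacs
#' vocabularies). The expected simulation time is the product of the time
#' step and the number of steps.
#'
#' Missing `dt` defaults to 0.001 ps and missing `nsteps` to 0, the Gromacs
#' runtime defaults. When several temperature-coupling groups are listed
#' under `ref_t`, the first value is taken as the starting temperature of the
#' system; a warning is recorded when the groups differ. Non-numeric `dt` or
#' `nsteps` mark the field absent (with a warning) rather than failing.
#'
#' @param params an `mdp_parameters` object from [parse_mdp()], or anything
#'   [parse_mdp()] accepts.
#' @return an object of class `mdp_summary`: list with `integrator`, `dt_ps`,
#'   `nsteps`, `ref_t_K`, `tcoupl_raw`, `pcoupl_raw`, `thermostat`,
#'   `barostat`, `sim_time_ns` and `warnings`. Absent fields are `NA`.
#' @examples
#' s <- summarize_mdp(parse_mdp("integrator = md\ndt = 0.002\nnsteps = 50000000"))
#' s$sim_time_ns  # 100
#' @export
summarize_mdp <- function(params) {
  if (!inherits(params, "mdp_parameters")) params <- parse_mdp(params)
  e <- params$entries
  warnings <- character(0)
  get <- function(key) if (key %in% names(e)) e[[key]] else NA_character_

  integrator <- tolower(as_scalar_chr(get("integrator")))

  dt_raw <- get("dt")
  if (is.na(dt_raw)) {
    dt_ps <- 0.001  # Gromacs default
  } else {
    dt_ps <- suppressWarnings(as.numeric(dt_raw))
    if (is.na(dt_ps)) warnings <- c(warnings, paste0("non-numeric dt: ", sQuote(dt_raw)))
  }

  nsteps_raw <- get("nsteps")
  if (is.na(nsteps_raw)) {
    nsteps <- 0
  } else {
    nsteps <- suppressWarnings(as.numeric(nsteps_raw))
    if (is.na(nsteps)) warnings <- c(warnings, paste0("non-numeric nsteps: ", sQuote(nsteps_raw)))
  }

  ref_t_raw <- get("ref_t")
  ref_t_K <- NA_real_
  if (!is.na(ref_t_raw)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ref_t_raw), "\\s+")[[1L]]))
    vals <- vals[!is.na(vals)]
    if (length(vals) >= 1L) {
      ref_t_K <- vals[1L]
      if (length(unique(vals)) > 1L) {
        warnings <- c(warnings, "ref_t groups differ; first value taken")
      }
    } else {
      warnings <- c(warnings, paste0("non-numeric ref_t: ", sQuote(ref_t_raw)))
    }
  }

  tcoupl_raw <- as_scalar_chr(get("tcoupl"))
  pcoupl_raw <- as_scalar_chr(get("pcoupl"))

  sim_time_ns <- if (!is.na(dt_ps) && !is.na(nsteps)) dt_ps * nsteps / 1000 else NA_real_

  structure(
    list(
      integrator = integrator,
      dt_ps = dt_ps,
      nsteps = nsteps,
      ref_t_K = ref_t_K,
      tcoupl_raw = tcoupl_raw,
      pcoupl_raw = pcoupl_raw,
      thermostat = normalize_thermostat(tcoupl_raw),
      barostat = normalize_barostat(pcoupl_raw),
      sim_time_ns = sim_time_ns,
      warnings = c(params$warnings, warnings)
    ),
    class = "mdp_summary"
  )
}

#' Bind .mdp summaries into a table
#'
#' One row per summary; list-columns are avoided so the result feeds the
#' report layer (cross-tabulations, histograms, time-split counts) directly.
#'
#' @param summaries a list of `mdp_summary` objects.
#' @return a data.frame with columns `integrator`, `dt_ps`, `nsteps`,
#'   `ref_t_K`, `thermostat`, `barostat`, `sim_time_ns`.
#' @export
mdp_summary_table <- function(summaries) {
  if (inherits(summaries, "mdp_summary")) summaries <- list(summaries)
  do.call(rbind, c(
    list(data.frame(
      integrator = character(0), dt_ps = numeric(0), nsteps = numeric(0),
      ref_t_K = numeric(0), thermostat = character(0), barostat = character(0),
      sim_time_ns = numeric(0), stringsAsFactors = FALSE
    )),
    lapply(summaries, function(s) data.frame(
      integrator = if (is.na(s$integrator)) NA_character_ else s$integrator,
      dt_ps = s$dt_ps, nsteps = s$nsteps, ref_t_K = s$ref_t_K,
      thermostat = s$thermostat, barostat = s$barostat,
      sim_time_ns = s$sim_time_ns, stringsAsFactors = FALSE
    ))
  ))
}

#' @export
print.mdp_summary <- function(x, ...) {
  cat("MD run parameters (.mdp)\n")
  cat("  integrator: ", if (is.na(x$integrator)) "<absent>" else x$integrator, "\n", sep = "")
  cat("  dt (ps):    ", x$dt_ps, "   nsteps: ", format(x$nsteps, scientific = FALSE), "\n", sep = "")
  cat("  sim time:   ", x$sim_time_ns, " ns\n", sep = "")
  cat("  thermostat: ", x$thermostat, "   barostat: ", x$barostat, "\n", sep = "")
  if (!is.na(x$ref_t_K)) cat("  ref_t (K):  ", x$ref_t_K, "\n", sep = "")
  invisible(x)
}
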