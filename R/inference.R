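# Rule-based metadata inference: engine assignment from file extensions,
# residue categorisation and system classification from .gro content,
# model-resolution and run-type labelling from .mdp content, and
# normalisation of thermostat/barostat values onto the documented Gromacs
# vocabularies.

THERMOSTAT_VOCAB <- c("no", "berendsen", "nose-hoover", "andersen",
                      "andersen-massive", "v-rescale")
BAROSTAT_VOCAB <- c("no", "berendsen", "c-rescale", "parrinello-rahman", "mttk")

# Coarse-grain time-step cutoff, ps. Martini-style coarse-grained set-ups
# integrate with dt of 10 fs or more; atomistic set-ups stay well below.
# The cutoff is inclusive: dt = 0.01 ps (10 fs) classifies as coarse-grain.
CG_DT_CUTOFF_PS <- 0.01

#' Assign a file to an MD engine from its extension
#'
#' Looks the extension up in the rule table. Rules whose extension is too
#' generic (`requires_keyword`) only fire when the dataset's free-text
#' metadata mentions molecular dynamics; extensions absent from the table
#' are always `"unknown"`.
#'
#' @param extension character vector of lowercase extensions (no dot; use
#'   [file_extension()]).
#' @param dataset_has_md_keyword logical vector (recycled) — whether the
#'   owning dataset's title+description matches an MD keyword.
#' @param rules an `engine_rules` table from [load_engine_rules()].
#' @return character vector of engine labels (`gromacs`, `amber`,
#'   `namd-charmm`, `desmond`) or `"unknown"`.
#' @examples
#' assign_engine(c("xtc", "psf", "txt"), TRUE)
#' @export
assign_engine <- function(extension, dataset_has_md_keyword = FALSE,
                          rules = load_engine_rules()) {
  n <- max(length(extension), length(dataset_has_md_keyword))
  extension <- rep_len(tolower(extension), n)
  k <- rep_len(as.logical(dataset_has_md_keyword), n)
  i <- match(extension, rules$extension)
  engine <- rules$engine[i]
  gated <- !is.na(i) & rules$requires_keyword[i] & !k
  engine[is.na(i) | gated] <- "unknown"
  engine
}

#' Categorise a residue name
#'
#' Case-insensitive lookup in the residue lexicon; residues not in the
#' lexicon are `"other"`.
#'
#' @param name character vector of residue names.
#' @param lexicon a `residue_lexicon` from [load_residue_lexicon()].
#' @return character vector of categories (`protein`, `lipid`, `nucleic`,
#'   `glucid`, `water_ions`, `other`).
#' @export
categorize_residue <- function(name, lexicon = load_residue_lexicon()) {
  if (any(!nzchar(trimws(name)))) stop("empty residue name", call. = FALSE)
  cat <- unname(lexicon[toupper(trimws(name))])
  cat[is.na(cat)] <- "other"
  cat
}

#' Classify a molecular system from its per-category particle counts
#'
#' The class label is the set of non-solvent categories present in the
#' system (particle count > 0), sorted and joined with `+` — e.g. a solvated
#' membrane protein is `"lipid+protein"`. Water/ions and unrecognised
#' (`other`) particles never contribute to the label set: systems with no
#' recognised solute are `"water/ions only"` when they contain water/ions
#' and nothing unrecognised, and `"other"` otherwise.
#'
#' @param category_counts named numeric vector of particle counts; names
#'   from `protein`, `lipid`, `nucleic`, `glucid`, `water_ions`, `other`
#'   (missing names count as zero).
#' @return a single class label.
#' @examples
#' classify_system(c(protein = 100, water_ions = 900))
#' classify_system(c(nucleic = 20, protein = 10))
#' @export
classify_system <- function(category_counts) {
  counts <- stats::setNames(numeric(6), c(RESIDUE_CATEGORIES, "other"))
  nm <- names(category_counts)
  if (length(category_counts) > 0L && is.null(nm)) {
    stop("category_counts must be named", call. = FALSE)
  }
  bad <- setdiff(nm, names(counts))
  if (length(bad) > 0L) {
    stop("unknown categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(category_counts < 0, na.rm = TRUE)) {
    stop("negative particle counts", call. = FALSE)
  }
  counts[nm] <- category_counts
  solute <- setdiff(RESIDUE_CATEGORIES, "water_ions")
  present <- sort(solute[counts[solute] > 0])
  if (length(present) > 0L) {
    paste(present, collapse = "+")
  } else if (counts[["water_ions"]] > 0 && counts[["other"]] == 0) {
    "water/ions only"
  } else {
    "other"
  }
}

#' Profile the molecular composition of a parsed .gro structure
#'
#' Tallies particles per residue category and labels the system class.
#'
#' @param gro a `gro_structure` from [parse_gro()].
#' @param lexicon a `residue_lexicon`.
#' @return an object of class `gro_summary`: list with `n_particles`,
#'   `category_counts` (named, categories plus `other`; sums to
#'   `n_particles`), `system_class` and `has_velocities`.
#' @export
summarize_composition <- function(gro, lexicon = load_residue_lexicon()) {
  stopifnot(inherits(gro, "gro_structure"))
  counts <- stats::setNames(numeric(6), c(RESIDUE_CATEGORIES, "other"))
  if (nrow(gro$atoms) > 0L) {
    tab <- table(categorize_residue(gro$atoms$residue_name, lexicon))
    counts[names(tab)] <- as.numeric(tab)
  }
  structure(
    list(
      n_particles = gro$declared_atom_count,
      category_counts = counts,
      system_class = classify_system(counts),
      has_velocities = gro$has_velocities
    ),
    class = "gro_summary"
  )
}

#' @export
print.gro_summary <- function(x, ...) {
  cat("Molecular system profile (.gro)\n")
  cat("  particles:", x$n_particles, "\n")
  cat("  class:    ", x$system_class, "\n")
  nz <- x$category_counts[x$category_counts > 0]
  if (length(nz) > 0L) {
    cat("  composition:\n")
    for (k in names(nz)) cat(sprintf("    %-10s %d\n", k, as.integer(nz[[k]])))
  }
  invisible(x)
}

#' Infer model resolution from the integration time step
#'
#' Coarse-grained models (Martini and kin) merge several atoms into one
#' interaction particle and can integrate with time steps of 10 fs and
#' above; atomistic set-ups use smaller steps. The cutoff is inclusive:
#' `dt_ps >= 0.01` (10 fs) is coarse-grain.
#'
#' @param dt_ps numeric vector of time steps in ps; `NA` for absent.
#' @return character vector: `"all-atom"`, `"coarse-grain"` or `"unknown"`.
#' @export
infer_resolution <- function(dt_ps) {
  out <- ifelse(dt_ps >= CG_DT_CUTOFF_PS, "coarse-grain", "all-atom")
  out[is.na(dt_ps)] <- "unknown"
  out
}

#' Label an .mdp set-up as production or not
#'
#' A production run integrates dynamics (`md` or `sd` integrator) for more
#' than `min_time_ns`. Energy minimisation (`steep`, `cg`, `l-bfgs`) is
#' never production, and neither is a set-up with neither thermostat nor
#' barostat coupling — those serve minimisation, ion placement or
#' MM/PBSA-style rescoring. Everything else (short dynamics, unusual
#' integrators) is `"unknown"`.
#'
#' @param summary an `mdp_summary` from [summarize_mdp()].
#' @param min_time_ns production time threshold, ns (default 1).
#' @return `"production"`, `"non-production"` or `"unknown"`.
#' @export
infer_run_type <- function(summary, min_time_ns = 1.0) {
  stopifnot(inherits(summary, "mdp_summary"))
  integ <- summary$integrator
  time_ok <- !is.na(summary$sim_time_ns) && summary$sim_time_ns > min_time_ns
  if (!is.na(integ) && integ %in% c("md", "sd") && time_ok) return("production")
  minimizer <- !is.na(integ) && integ %in% c("steep", "cg", "l-bfgs")
  uncoupled <- summary$thermostat %in% c("undefined", "no") &&
    summary$barostat %in% c("undefined", "no")
  if (minimizer || uncoupled) return("non-production")
  "unknown"
}

#' @noRd
normalize_coupling <- function(raw, vocab) {
  out <- rep("unrecognized", length(raw))
  low <- tolower(trimws(as.character(raw)))
  out[low %in% vocab] <- low[low %in% vocab]
  # already-normalised sentinels pass through (idempotence)
  out[low %in% c("undefined", "unrecognized")] <- low[low %in% c("undefined", "unrecognized")]
  out[is.na(raw)] <- "undefined"
  out
}

#' Normalise a thermostat value onto the documented Gromacs vocabulary
#'
#' Case-insensitive mapping onto `no`, `berendsen`, `nose-hoover`,
#' `andersen`, `andersen-massive`, `v-rescale`. Absent values are
#' `"undefined"`; anything else is `"unrecognized"`. Idempotent.
#'
#' @param raw character vector of raw `tcoupl` tokens; `NA` for absent.
#' @return character vector of vocabulary values.
#' @export
normalize_thermostat <- function(raw) {
  normalize_coupling(raw, THERMOSTAT_VOCAB)
}

#' Normalise a barostat value onto the documented Gromacs vocabulary
#'
#' Case-insensitive mapping onto `no`, `berendsen`, `c-rescale`,
#' `parrinello-rahman`, `mttk`. Absent values are `"undefined"`; anything
#' else is `"unrecognized"`. Idempotent.
#'
#' @param raw character vector of raw `pcoupl` tokens; `NA` for absent.
#' @return character vector of vocabulary values.
#' @export
normalize_barostat <- function(raw) {
  normalize_coupling(raw, BAROSTAT_VOCAB)
}
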