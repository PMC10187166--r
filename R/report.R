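# Aggregation and statistics over a harvest index: corpus-level summary
# tables, distributions, the thermostat x barostat cross-tabulation, the
# production-time split, and the search/filter/export behaviour of the data
# explorer.

#' Per-repository corpus statistics
#'
#' One row per repository — dataset count, first/latest deposition date,
#' loose file count, total size, zip-archive count, in-zip file count and
#' grand file total — plus a `Total` row whose every numeric cell is the
#' exact column sum (sizes are summed in bytes and converted once).
#' Sizes are decimal gigabytes (1 GB = 10^9 bytes), the unit repositories
#' themselves report.
#'
#' @param index a `harvest_index`.
#' @return data.frame with columns `repository`, `dataset_count`,
#'   `first_date`, `last_date`, `loose_file_count`, `total_size_gb`,
#'   `zip_file_count`, `in_zip_file_count`, `total_file_count`.
#' @export
tabulate_by_repository <- function(index) {
  stopifnot(inherits(index, "harvest_index"))
  repos <- sort(unique(index$datasets$repository))

  row_for <- function(repo) {
    ds <- index$datasets[index$datasets$repository == repo, , drop = FALSE]
    f <- index$files[index$files$repository == repo, , drop = FALSE]
    loose <- f[!f$from_zip, , drop = FALSE]
    data.frame(
      repository = repo,
      dataset_count = nrow(ds),
      first_date = if (nrow(ds) > 0L) min(ds$created_date) else NA_character_,
      last_date = if (nrow(ds) > 0L) max(ds$created_date) else NA_character_,
      loose_file_count = nrow(loose),
      size_bytes = sum(loose$size_bytes, na.rm = TRUE),
      zip_file_count = sum(loose$extension == "zip"),
      in_zip_file_count = sum(f$from_zip),
      total_file_count = nrow(f),
      stringsAsFactors = FALSE
    )
  }
  rows <- do.call(rbind, c(list(row_for("")[0, ]), lapply(repos, row_for)))

  total <- data.frame(
    repository = "Total",
    dataset_count = sum(rows$dataset_count),
    first_date = NA_character_,
    last_date = NA_character_,
    loose_file_count = sum(rows$loose_file_count),
    size_bytes = sum(rows$size_bytes),
    zip_file_count = sum(rows$zip_file_count),
    in_zip_file_count = sum(rows$in_zip_file_count),
    total_file_count = sum(rows$total_file_count),
    stringsAsFactors = FALSE
  )
  out <- rbind(rows, total)
  out$total_size_gb <- out$size_bytes / 1e9
  out$size_bytes <- NULL
  out <- out[, c("repository", "dataset_count", "first_date", "last_date",
                 "loose_file_count", "total_size_gb", "zip_file_count",
                 "in_zip_file_count", "total_file_count")]
  rownames(out) <- NULL
  out
}

#' Deposited files per year and repository
#'
#' Every file (loose or inside a zip) is counted under the deposition year
#' of its dataset — files carry no dates of their own in repository
#' previews.
#'
#' @param index a `harvest_index`.
#' @return data.frame with columns `year` (integer), `repository`,
#'   `n_files`, sorted by year then repository. Empty index gives zero rows.
#' @export
files_per_year <- function(index) {
  stopifnot(inherits(index, "harvest_index"))
  if (nrow(index$files) == 0L) {
    return(data.frame(year = integer(0), repository = character(0),
                      n_files = integer(0), stringsAsFactors = FALSE))
  }
  dkey <- paste(index$datasets$repository, index$datasets$dataset_id, sep = "\r")
  fkey <- paste(index$files$repository, index$files$dataset_id, sep = "\r")
  date <- index$datasets$created_date[match(fkey, dkey)]
  if (anyNA(date)) stop("files_per_year: datasets without created_date", call. = FALSE)
  year <- as.integer(substr(date, 1L, 4L))
  tab <- as.data.frame(table(year = year, repository = index$files$repository),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  out <- data.frame(year = as.integer(tab$year), repository = tab$repository,
                    n_files = as.integer(tab$Freq), stringsAsFactors = FALSE)
  out <- out[order(out$year, out$repository), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
file_engines <- function(index, rules, keywords) {
  has_kw <- has_md_keyword(paste(index$datasets$title, index$datasets$description),
                           keywords)
  dkey <- paste(index$datasets$repository, index$datasets$dataset_id, sep = "\r")
  fkey <- paste(index$files$repository, index$files$dataset_id, sep = "\r")
  assign_engine(index$files$extension, has_kw[match(fkey, dkey)], rules)
}

#' Distribution of files across MD engines
#'
#' Every file in the index is assigned to an engine from its extension
#' (keyword-gated rules consult the owning dataset's metadata); counts sum
#' to the total number of files.
#'
#' @param index a `harvest_index`.
#' @param rules an `engine_rules` table.
#' @param keywords MD keyword list.
#' @return named integer vector over `gromacs`, `amber`, `namd-charmm`,
#'   `desmond`, `unknown`.
#' @export
engine_distribution <- function(index, rules = load_engine_rules(),
                                keywords = load_md_keywords()) {
  stopifnot(inherits(index, "harvest_index"))
  labels <- c(ENGINE_LABELS, "unknown")
  counts <- stats::setNames(integer(length(labels)), labels)
  if (nrow(index$files) == 0L) return(counts)
  tab <- table(factor(file_engines(index, rules, keywords), levels = labels))
  counts[] <- as.integer(tab)
  counts
}

#' Most frequent extensions among engine-unknown files
#'
#' Expands the `unknown` engine bucket into its `n` most observed file
#' types. `"none"` (extension-less files) is a valid bucket. Ties are broken
#' by lexicographic extension order so the result is deterministic.
#'
#' @param index a `harvest_index`.
#' @param n number of extensions to return (all of them when fewer exist).
#' @param rules,keywords engine assignment configuration.
#' @return data.frame with columns `extension`, `n_files`, ordered by
#'   decreasing count then extension.
#' @export
unknown_extension_top <- function(index, n = 10L, rules = load_engine_rules(),
                                  keywords = load_md_keywords()) {
  stopifnot(inherits(index, "harvest_index"), n >= 1L)
  if (nrow(index$files) == 0L) {
    return(data.frame(extension = character(0), n_files = integer(0),
                      stringsAsFactors = FALSE))
  }
  eng <- file_engines(index, rules, keywords)
  ext <- index$files$extension[eng == "unknown"]
  if (length(ext) == 0L) {
    return(data.frame(extension = character(0), n_files = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(ext)
  out <- data.frame(extension = names(tab), n_files = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_files, out$extension), , drop = FALSE]
  out <- utils::head(out, n)
  rownames(out) <- NULL
  out
}

#' Empirical cumulative distribution on distinct values
#'
#' The standard ECDF, tabulated at the sorted distinct values: the fraction
#' at value v is P(X <= v). Fractions are non-decreasing and end at 1 for
#' non-empty input; counts are conserved.
#'
#' @param values finite numeric vector.
#' @return data.frame with columns `value` (sorted distinct) and `fraction`.
#' @examples
#' ecdf_table(c(1, 2, 2, 4))
#' @export
ecdf_table <- function(values) {
  if (length(values) == 0L) {
    return(data.frame(value = numeric(0), fraction = numeric(0)))
  }
  if (any(!is.finite(values))) stop("ecdf_table: non-finite values", call. = FALSE)
  v <- sort(unique(values))
  data.frame(value = v, fraction = stats::ecdf(values)(v))
}

#' Thermostat x barostat cross-tabulation
#'
#' Counts .mdp files over normalised (thermostat, barostat) pairs — the data
#' behind a coupling-choices Sankey/flow diagram. The grand total equals the
#' number of contributing files. Files with neither coupling defined
#' (`undefined` x `undefined`) form the no-coupling group, reported
#' separately in attribute `"no_coupling"` — these set-ups would not be used
#' for production runs.
#'
#' @param summaries data.frame from [mdp_summary_table()] (or a list of
#'   `mdp_summary` objects).
#' @return a contingency `table` (thermostat rows, barostat columns) over
#'   the full vocabularies plus `undefined`/`unrecognized`, with the
#'   no-coupling count in attribute `"no_coupling"`.
#' @export
crosstab_thermo_baro <- function(summaries) {
  df <- as_mdp_table(summaries)
  t_levels <- c(THERMOSTAT_VOCAB, "undefined", "unrecognized")
  b_levels <- c(BAROSTAT_VOCAB, "undefined", "unrecognized")
  tab <- table(
    thermostat = factor(df$thermostat, levels = t_levels),
    barostat = factor(df$barostat, levels = b_levels)
  )
  attr(tab, "no_coupling") <- as.integer(tab["undefined", "undefined"])
  tab
}

#' @noRd
as_mdp_table <- function(summaries) {
  if (is.data.frame(summaries)) summaries else mdp_summary_table(summaries)
}

#' Share of Gromacs files that are trajectories
#'
#' Trajectory files (`.xtc` compressed and `.trr` full-precision) as a
#' fraction of all Gromacs-assigned files in the index. The percentage is
#' rounded half-away-from-zero to the nearest integer.
#'
#' @param index a `harvest_index`.
#' @param rules,keywords engine assignment configuration.
#' @return list with `n_trajectory`, `n_gromacs`, `fraction`, `percent`.
#' @export
trajectory_share <- function(index, rules = load_engine_rules(),
                             keywords = load_md_keywords()) {
  stopifnot(inherits(index, "harvest_index"))
  eng <- if (nrow(index$files) > 0L) file_engines(index, rules, keywords) else character(0)
  gmx <- index$files$extension[eng == "gromacs"]
  n_gmx <- length(gmx)
  if (n_gmx == 0L) {
    stop("trajectory_share: no Gromacs-assigned files in the index", call. = FALSE)
  }
  n_traj <- sum(gmx %in% c("xtc", "trr"))
  frac <- n_traj / n_gmx
  list(n_trajectory = n_traj, n_gromacs = n_gmx, fraction = frac,
       percent = as.integer(round_half_away(100 * frac)))
}

#' Histogram of simulation starting temperatures
#'
#' Bins the reference temperatures of .mdp files into fixed-width,
#' left-closed right-open bins `[lo, lo + width)`. Files without a
#' temperature are excluded; the total count over bins equals the number of
#' files with one.
#'
#' @param summaries data.frame from [mdp_summary_table()] or list of
#'   `mdp_summary`.
#' @param bin_width_K bin width in kelvin (default 2).
#' @return data.frame with columns `bin_lo`, `bin_hi`, `count` (only
#'   non-empty bins).
#' @export
temperature_histogram <- function(summaries, bin_width_K = 2) {
  stopifnot(bin_width_K > 0)
  df <- as_mdp_table(summaries)
  t <- df$ref_t_K[!is.na(df$ref_t_K)]
  if (length(t) == 0L) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0), count = integer(0)))
  }
  lo <- floor(t / bin_width_K) * bin_width_K
  tab <- table(lo)
  out <- data.frame(
    bin_lo = as.numeric(names(tab)),
    bin_hi = as.numeric(names(tab)) + bin_width_K,
    count = as.integer(tab)
  )
  out[order(out$bin_lo), , drop = FALSE]
}

# Simulation-time bands for the production-run analysis, in ns. The first
# band is closed on the right: a set-up of exactly 50 ns counts as <=50 ns.
TIME_BANDS_NS <- c(50, 1000)
TIME_BAND_LABELS <- c("<=50 ns", "50 ns - 1 us", ">1 us")

#' Production set-ups split by model resolution and simulation-time band
#'
#' Counts only files labelled production (`md`/`sd` integrator, simulation
#' time above 1 ns), split by inferred resolution (all-atom vs coarse-grain
#' from the time step) and by set-up time band: at most 50 ns, 50 ns to
#' 1 us, above 1 us.
#'
#' @param summaries data.frame from [mdp_summary_table()] or list of
#'   `mdp_summary`; needs columns `integrator`, `dt_ps`, `sim_time_ns`,
#'   `thermostat`, `barostat`.
#' @param min_time_ns production threshold passed to the run-type rule.
#' @return a contingency `table` with resolution rows and time-band columns;
#'   attribute `"n_production"` holds the production file count.
#' @export
production_time_split <- function(summaries, min_time_ns = 1.0) {
  df <- as_mdp_table(summaries)
  run_type <- vapply(seq_len(nrow(df)), function(i) {
    s <- structure(as.list(df[i, , drop = FALSE]), class = "mdp_summary")
    infer_run_type(s, min_time_ns)
  }, character(1))
  prod <- df[run_type == "production", , drop = FALSE]

  band <- cut(prod$sim_time_ns, breaks = c(-Inf, TIME_BANDS_NS, Inf),
              labels = TIME_BAND_LABELS, right = TRUE)
  res <- factor(infer_resolution(prod$dt_ps),
                levels = c("all-atom", "coarse-grain", "unknown"))
  tab <- table(resolution = res, band = band)
  attr(tab, "n_production") <- nrow(prod)
  tab
}

#' Search the index with keywords and filters
#'
#' Case-insensitive conjunctive matching: `text_query` must occur as a
#' substring of a dataset's title + description, and every filter must hold.
#' Supported filters: `repository`, `extension` (set membership), `engine`
#' (set membership after assignment), `date_from`, `date_to` (on the
#' dataset's deposition date), `from_zip` (logical), `min_size_bytes`,
#' `max_size_bytes`. With no query and no filters the whole index is
#' returned; adding a predicate never enlarges the result. Output ordering
#' is deterministic: repository, dataset id, file name.
#'
#' @param index a `harvest_index`.
#' @param text_query optional phrase.
#' @param filters named list of predicates (see above).
#' @param rules,keywords engine assignment configuration (only consulted for
#'   the `engine` filter).
#' @return a `harvest_index` restricted to the matching datasets and their
#'   matching files.
#' @export
search_index <- function(index, text_query = NULL, filters = list(),
                         rules = load_engine_rules(),
                         keywords = load_md_keywords()) {
  stopifnot(inherits(index, "harvest_index"))
  known <- c("repository", "extension", "engine", "date_from", "date_to",
             "from_zip", "min_size_bytes", "max_size_bytes")
  bad <- setdiff(names(filters), known)
  if (length(bad) > 0L) {
    stop("search_index: unknown filters: ", paste(bad, collapse = ", "), call. = FALSE)
  }

  ds <- index$datasets
  keep_ds <- rep(TRUE, nrow(ds))
  if (!is.null(text_query) && nzchar(text_query)) {
    hay <- tolower(paste(ds$title, ds$description))
    keep_ds <- keep_ds & grepl(tolower(text_query), hay, fixed = TRUE)
  }
  if (!is.null(filters$repository)) keep_ds <- keep_ds & ds$repository %in% filters$repository
  if (!is.null(filters$date_from)) keep_ds <- keep_ds & ds$created_date >= filters$date_from
  if (!is.null(filters$date_to)) keep_ds <- keep_ds & ds$created_date <= filters$date_to

  ds <- ds[keep_ds, , drop = FALSE]
  dkey <- paste(ds$repository, ds$dataset_id, sep = "\r")
  f <- index$files
  f <- f[paste(f$repository, f$dataset_id, sep = "\r") %in% dkey, , drop = FALSE]

  if (!is.null(filters$extension)) f <- f[f$extension %in% tolower(filters$extension), , drop = FALSE]
  if (!is.null(filters$from_zip)) f <- f[f$from_zip == filters$from_zip, , drop = FALSE]
  if (!is.null(filters$min_size_bytes)) {
    f <- f[!is.na(f$size_bytes) & f$size_bytes >= filters$min_size_bytes, , drop = FALSE]
  }
  if (!is.null(filters$max_size_bytes)) {
    f <- f[!is.na(f$size_bytes) & f$size_bytes <= filters$max_size_bytes, , drop = FALSE]
  }
  if (!is.null(filters$engine)) {
    sub <- harvest_index(index$datasets, f, index$manifest)
    f <- f[file_engines(sub, rules, keywords) %in% filters$engine, , drop = FALSE]
  }

  ds <- ds[order(ds$repository, ds$dataset_id), , drop = FALSE]
  f <- f[order(f$repository, f$dataset_id, f$file_name), , drop = FALSE]
  harvest_index(ds, f, index$manifest)
}

#' Export a table as tab-separated values
#'
#' UTF-8, header row, tab separators, newline-terminated rows. Tabs and
#' newlines embedded in free-text cells are replaced by single spaces so the
#' file stays rectangular on re-import.
#'
#' @param table a data.frame.
#' @param destination output file path.
#' @return `destination`, invisibly.
#' @export
export_tsv <- function(table, destination) {
  stopifnot(is.data.frame(table))
  sane <- table
  for (col in names(sane)) {
    if (is.character(sane[[col]])) {
      sane[[col]] <- gsub("[\t\r\n]+", " ", sane[[col]])
    } else if (is.factor(sane[[col]])) {
      sane[[col]] <- gsub("[\t\r\n]+", " ", as.character(sane[[col]]))
    }
  }
  utils::write.table(sane, destination, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(destination)
}
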