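# Deterministic synthetic generators for every input the pipeline consumes:
# .gro / .mdp / .xtc files, mock repository adapters, and whole harvest
# indices with known marginal counts. Each generator returns its own ground
# truth, so parse(make_X(spec)) == truth is the testing contract for the
# parsers (generator/parser adjunction). All generators are pure functions
# of their spec, seed included; none touches the caller's RNG state.
#
# Coordinates and payload bytes are pseudo-random and physically
# meaningless on purpose: the parsers never inspect values beyond format
# validity, and emulating force fields is a non-goal.

# per-category residue templates: residue name + atom names of one molecule
GRO_TEMPLATES <- list(
  water_ions = list(resname = "SOL", atom_names = c("OW", "HW1", "HW2")),
  protein = list(resname = "ALA",
                 atom_names = c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "C")),
  lipid = list(resname = "POPC", atom_names = paste0("C", 1:50)),
  nucleic = list(resname = "DA",
                 atom_names = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                                "C3'", "O3'", "C2'", "C1'", "N9", "C8", "N7",
                                "C5", "C6", "N6", "N1", "C2", "N3")),
  glucid = list(resname = "GLC",
                atom_names = c("C1", "C2", "C3", "C4", "C5", "C6",
                               "O1", "O2", "O3", "O4", "O5", "O6"))
)

#' Generate a synthetic Gromacs .gro file with known composition
#'
#' Builds a format-valid .gro file from per-category molecule counts, using
#' fixed residue templates: water/ions are 3-atom SOL molecules, a generic
#' protein residue has 8 atoms, a lipid 50, a nucleic residue 20 and a sugar
#' 12. `extra_templates` is a free-form hook for additional molecule types
#' (e.g. residues outside the lexicon, to exercise the `other` category).
#' Molecule order is shuffled deterministically under `seed`; coordinates
#' are uniform pseudo-random positions inside the box.
#'
#' @param composition named vector of molecule counts; names from
#'   `water_ions`, `protein`, `lipid`, `nucleic`, `glucid` or the names of
#'   `extra_templates`.
#' @param box_nm box vector lengths in nm (3 values).
#' @param with_velocities also emit the three velocity fields.
#' @param seed integer seed; same spec + seed give byte-identical output.
#' @param extra_templates named list of
#'   `list(resname =, atom_names =, category =)` entries; `category`
#'   defaults to `"other"`.
#' @param title title line text.
#' @return list with `text` (the file, single string), `summary` (ground
#'   truth: `n_particles`, `category_counts`, `system_class`,
#'   `has_velocities`), and `residue_names` (per-atom, in file order).
#' @examples
#' fx <- make_gro(c(protein = 10, water_ions = 100), seed = 1)
#' fx$summary$n_particles  # 10*8 + 100*3 = 380
#' @export
make_gro <- function(composition, box_nm = c(5, 5, 5), with_velocities = FALSE,
                     seed = 1L, extra_templates = NULL, title = "synthetic system") {
  stopifnot(length(box_nm) == 3L, all(box_nm > 0))
  templates <- GRO_TEMPLATES
  if (!is.null(extra_templates)) {
    for (nm in names(extra_templates)) {
      t <- extra_templates[[nm]]
      templates[[nm]] <- list(resname = t$resname, atom_names = t$atom_names,
                              category = t$category %||% "other")
    }
  }
  comp <- composition[composition > 0]
  bad <- setdiff(names(comp), names(templates))
  if (length(bad) > 0L) {
    stop("make_gro: no template for: ", paste(bad, collapse = ", "), call. = FALSE)
  }

  # one row per molecule, then shuffled; per-atom columns built vectorised
  mol_kind <- rep(names(comp), times = as.integer(comp))
  if (length(mol_kind) == 0L) stop("make_gro: empty composition", call. = FALSE)
  with_seed(seed, {
    mol_kind <- if (length(mol_kind) > 1L) sample(mol_kind) else mol_kind

    atoms_per <- vapply(templates, function(t) length(t$atom_names), integer(1))
    n_at_mol <- unname(atoms_per[mol_kind])
    mol_of_atom <- rep(seq_along(mol_kind), times = n_at_mol)
    res_names <- unlist(lapply(mol_kind, function(k) {
      rep(templates[[k]]$resname, atoms_per[[k]])
    }), use.names = FALSE)
    atom_names <- unlist(lapply(mol_kind, function(k) templates[[k]]$atom_names),
                         use.names = FALSE)
    n_total <- length(res_names)

    categories <- vapply(names(templates), function(k) {
      templates[[k]]$category %||% k
    }, character(1))
    counts <- stats::setNames(numeric(6), c(RESIDUE_CATEGORIES, "other"))
    for (k in unique(mol_kind)) {
      counts[[categories[[k]]]] <- counts[[categories[[k]]]] +
        sum(mol_kind == k) * atoms_per[[k]]
    }

    xyz <- matrix(stats::runif(3L * n_total), ncol = 3L) %*% diag(box_nm)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     mol_of_atom %% 100000L, res_names, atom_names,
                     seq_len(n_total) %% 100000L,
                     xyz[, 1L], xyz[, 2L], xyz[, 3L])
    if (with_velocities) {
      vel <- matrix(stats::runif(3L * n_total, -1, 1), ncol = 3L)
      lines <- paste0(lines, sprintf("%8.4f%8.4f%8.4f",
                                     vel[, 1L], vel[, 2L], vel[, 3L]))
    }
  })
  n_particles <- length(lines)
  text <- paste0(paste(c(
    title,
    sprintf("%5d", n_particles),
    lines,
    sprintf("%10.5f%10.5f%10.5f", box_nm[1L], box_nm[2L], box_nm[3L])
  ), collapse = "\n"), "\n")

  list(
    text = text,
    summary = list(
      n_particles = n_particles,
      category_counts = counts,
      system_class = classify_system(counts),
      has_velocities = isTRUE(with_velocities)
    ),
    residue_names = res_names,
    box = box_nm
  )
}

#' Render .mdp entries in dialect variations
#'
#' Emits the same logical entries in one of four styles, to exercise the
#' parser's normalisation: `spaced` (`key = value`), `compact`
#' (`key=value`), `mixed-case` (capitalised keys with `_` rendered as `-`,
#' e.g. `Ref-T`), `commented` (spaced, with `;` comments appended and
#' interleaved). Parsing any style yields identical normalised entries.
#'
#' @param entries named character vector (keys in normalised form).
#' @param style one of `"spaced"`, `"compact"`, `"mixed-case"`,
#'   `"commented"`.
#' @return the .mdp file as a single string.
#' @export
make_mdp <- function(entries,
                     style = c("spaced", "compact", "mixed-case", "commented")) {
  style <- match.arg(style)
  keys <- names(entries)
  vals <- as.character(entries)
  lines <- switch(
    style,
    spaced = paste(keys, "=", vals),
    compact = paste0(keys, "=", vals),
    "mixed-case" = {
      shown <- vapply(keys, function(k) {
        k <- gsub("_", "-", k, fixed = TRUE)
        paste0(toupper(substr(k, 1L, 1L)), substr(k, 2L, nchar(k)))
      }, character(1))
      paste(shown, "=", vals)
    },
    commented = {
      body <- paste(keys, "=", vals, "; set by generator")
      as.vector(rbind("; generated parameter block", body))
    }
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Generate a synthetic .xtc byte stream with known frame structure
#'
#' Emits structurally valid XDR frames: magic 1995, atom count, step, time
#' (2 ps apart), a nine-float box, and a coordinate block of the correct
#' advertised size — uncompressed floats for up to 9 atoms, otherwise a
#' compressed-block layout whose payload is arbitrary bytes of the declared
#' (padded) length. The payload is not a real compressed stream: frame
#' counting never decompresses coordinates.
#'
#' @param n_atoms atoms per frame (>= 1).
#' @param n_frames number of frames to emit.
#' @param seed integer seed (payload bytes and block sizes).
#' @param truncate_last cut the final frame short, leaving a partial frame.
#' @param bad_magic corrupt the first frame's magic number (for error-path
#'   fixtures).
#' @return list with `bytes` (raw vector) and `summary` (ground truth:
#'   `n_atoms`, `n_frames` counted as complete, `first_time_ps`,
#'   `last_time_ps`, `truncated`).
#' @export
make_xtc <- function(n_atoms, n_frames, seed = 1L, truncate_last = FALSE,
                     bad_magic = FALSE) {
  stopifnot(n_atoms >= 1L, n_frames >= 0L)
  if (truncate_last && n_frames < 1L) {
    stop("make_xtc: cannot truncate an empty stream", call. = FALSE)
  }
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con))
    magic <- if (bad_magic && i == 1L) 1234L else XTC_MAGIC
    writeBin(c(magic, as.integer(n_atoms), i - 1L), con, size = 4L, endian = "big")
    writeBin(as.numeric((i - 1L) * 2.0), con, size = 4L, endian = "big")  # time, ps
    writeBin(stats::runif(9), con, size = 4L, endian = "big")             # box
    if (n_atoms <= 9L) {
      writeBin(stats::runif(3L * n_atoms), con, size = 4L, endian = "big")
    } else {
      nbytes <- 3L * as.integer(n_atoms) + sample.int(40L, 1L)
      writeBin(as.integer(n_atoms), con, size = 4L, endian = "big")       # lsize
      writeBin(1000.0, con, size = 4L, endian = "big")                    # precision
      writeBin(sample.int(1000L, 6L), con, size = 4L, endian = "big")     # min/max ints
      writeBin(c(5L, nbytes), con, size = 4L, endian = "big")             # smallidx, nbytes
      padded <- 4L * ((nbytes + 3L) %/% 4L)
      writeBin(as.raw(sample.int(256L, padded, replace = TRUE) - 1L), con)
    }
    rawConnectionValue(con)
  }))

  n_complete <- n_frames
  truncated <- FALSE
  if (truncate_last) {
    last <- frames[[n_frames]]
    # keep header plus part of the box: a recognisable partial frame
    frames[[n_frames]] <- last[seq_len(min(length(last), 26L))]
    n_complete <- n_frames - 1L
    truncated <- TRUE
  }
  bytes <- do.call(c, c(list(raw(0)), frames))

  times <- if (n_complete >= 1L) c(0, (n_complete - 1L) * 2.0) else c(NA_real_, NA_real_)
  list(
    bytes = bytes,
    summary = list(
      n_atoms = as.integer(n_atoms),
      n_frames = as.integer(n_complete),
      first_time_ps = times[1L],
      last_time_ps = times[2L],
      truncated = truncated
    )
  )
}

#' Render a zip-archive preview page in a repository dialect
#'
#' Produces the HTML structure [parse_zip_preview()] understands, capped at
#' `cap` entries when given.
#'
#' @param entries data.frame with `path` and `size_bytes`, or a character
#'   vector of paths.
#' @param dialect `"zenodo"` (table-based) or `"figshare"` (list-based).
#' @param cap maximum number of entries to render (`NA` for no cap).
#' @return HTML text (single string).
#' @export
make_zip_preview <- function(entries, dialect = c("zenodo", "figshare"),
                             cap = NA_integer_) {
  dialect <- match.arg(dialect)
  if (is.character(entries)) {
    entries <- data.frame(path = entries, size_bytes = NA_real_,
                          stringsAsFactors = FALSE)
  }
  if (!is.na(cap)) entries <- utils::head(entries, cap)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  size_txt <- ifelse(is.na(entries$size_bytes), "",
                     format(entries$size_bytes, scientific = FALSE, trim = TRUE))
  if (dialect == "zenodo") {
    rows <- sprintf("    <tr><td class=\"name\">%s</td><td class=\"size\">%s</td></tr>",
                    esc(entries$path), size_txt)
    body <- paste0("<table class=\"zip-listing\">\n  <tbody>\n",
                   paste(rows, collapse = "\n"),
                   "\n  </tbody>\n</table>")
  } else {
    items <- sprintf("  <li data-size=\"%s\">%s</li>", size_txt, esc(entries$path))
    body <- paste0("<ul class=\"archive-preview\">\n",
                   paste(items, collapse = "\n"), "\n</ul>")
  }
  paste0("<html><body>\n", body, "\n</body></html>\n")
}

#' Build a mock repository adapter from an in-memory specification
#'
#' The adapter honours the harvester contract (`search`, `fetch_dataset`,
#' `fetch_zip_listing`) entirely from the spec: searches match a query's
#' file type against loose-file extensions and its keyword against
#' title+description (case-insensitive substring); zip listings are served
#' by rendering the dialect's preview HTML (capped at `preview_cap`
#' entries) and parsing it back through [parse_zip_preview()], so the mock
#' exercises the same code path a live adapter would. A `NULL` dialect
#' models repositories without zip previews.
#'
#' @param spec list with `name`, optional `dialect` (`"zenodo"`,
#'   `"figshare"` or `NULL`), optional `preview_cap` (defaults to the
#'   dialect cap), and `datasets`: a list of entries with `dataset_id`,
#'   `title`, `description`, `created_date`, optional `doi`/`license`,
#'   `files` (list of `list(name =, size_bytes =)`), and optional `zips`
#'   (list of `list(name =, size_bytes =, entries =)` where `entries` is a
#'   character vector of member paths or a data.frame with `path`,
#'   `size_bytes`).
#' @return an adapter: list with `name`, `dialect`, `search`,
#'   `fetch_dataset`, `fetch_zip_listing`; class `repo_adapter`.
#' @export
make_mock_repository <- function(spec) {
  stopifnot(is.list(spec), is.character(spec$name))
  name <- spec$name
  dialect <- spec$dialect %||% NULL
  if (!is.null(dialect)) dialect <- match.arg(dialect, c("zenodo", "figshare"))
  cap <- spec$preview_cap %||%
    (if (is.null(dialect)) NA_integer_ else ZIP_PREVIEW_CAPS[[dialect]])
  datasets <- spec$datasets %||% list()
  ids <- vapply(datasets, function(d) as.character(d$dataset_id), character(1))
  names(datasets) <- ids

  loose_names <- function(d) {
    c(vapply(d$files %||% list(), function(f) as.character(f$name), character(1)),
      vapply(d$zips %||% list(), function(z) as.character(z$name), character(1)))
  }

  search <- function(query) {
    stopifnot(inherits(query, "query_spec"))
    hit <- vapply(datasets, function(d) {
      exts <- file_extension(loose_names(d))
      if (!(query$file_type %in% exts)) return(FALSE)
      if (is.null(query$keyword)) return(TRUE)
      grepl(tolower(query$keyword),
            tolower(paste(d$title %||% "", d$description %||% "")), fixed = TRUE)
    }, logical(1))
    unname(ids[hit])
  }

  fetch_dataset <- function(dataset_id) {
    d <- datasets[[as.character(dataset_id)]]
    if (is.null(d)) {
      stop(sprintf("dataset %s not found in %s", sQuote(dataset_id), name),
           call. = FALSE)
    }
    all_files <- c(d$files %||% list(), d$zips %||% list())
    files <- data.frame(
      file_name = vapply(all_files, function(f) as.character(f$name), character(1)),
      size_bytes = vapply(all_files, function(f) as.numeric(f$size_bytes %||% NA_real_),
                          numeric(1)),
      download_url = rep(NA_character_, length(all_files)),
      stringsAsFactors = FALSE
    )
    dataset <- data.frame(
      repository = name,
      dataset_id = as.character(dataset_id),
      doi = as.character(d$doi %||% NA_character_),
      title = as.character(d$title %||% ""),
      description = as.character(d$description %||% ""),
      created_date = as.character(d$created_date %||% NA_character_),
      license = as.character(d$license %||% NA_character_),
      stringsAsFactors = FALSE
    )
    list(dataset = dataset, files = files)
  }

  fetch_zip_listing <- function(dataset_id, file_name) {
    if (is.null(dialect)) return(zip_listing(supported = FALSE))
    d <- datasets[[as.character(dataset_id)]]
    if (is.null(d)) stop("dataset not found", call. = FALSE)
    z <- NULL
    for (cand in d$zips %||% list()) if (identical(cand$name, file_name)) z <- cand
    if (is.null(z)) stop("zip not found: ", file_name, call. = FALSE)
    entries <- z$entries
    if (is.character(entries)) {
      entries <- data.frame(path = entries, size_bytes = NA_real_,
                            stringsAsFactors = FALSE)
    }
    markup <- make_zip_preview(entries, dialect, cap = cap)
    listing <- parse_zip_preview(markup, dialect)
    # the spec's cap may differ from the dialect default
    listing$truncated <- !is.na(cap) && nrow(listing$entries) == cap &&
      nrow(entries) >= cap
    listing
  }

  structure(
    list(name = name, dialect = dialect, preview_cap = cap,
         search = search, fetch_dataset = fetch_dataset,
         fetch_zip_listing = fetch_zip_listing),
    class = "repo_adapter"
  )
}

#' Load a mock repository specification from JSON
#'
#' Mock-repo fixtures can live as plain JSON files; this reads one and
#' builds the adapter.
#'
#' @param path JSON file with the [make_mock_repository()] spec structure.
#' @return a `repo_adapter`.
#' @export
read_mock_repository <- function(path) {
  make_mock_repository(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Generate a synthetic harvest index with exact marginal counts
#'
#' Builds an index whose per-repository marginals — dataset count, loose
#' files per extension, zip-archive count (the `"zip"` extension key),
#' in-zip files per extension, total loose size in bytes, first/latest
#' deposition dates — match the profile exactly, for report-layer oracle
#' tests. Loose sizes are distributed so they sum to `total_loose_bytes`
#' exactly; in-zip files carry no sizes (previews rarely report them);
#' files are assigned to datasets round-robin and in-zip entries to zip
#' parents round-robin.
#'
#' @param profile list of per-repository specs:
#'   `list(repository =, n_datasets =, date_from =, date_to =,`
#'   `loose_ext_counts = c(ext = count, ...), in_zip_ext_counts = c(...),`
#'   `total_loose_bytes =, md_keyword = TRUE)`.
#' @param seed integer seed (dataset date jitter only; counts are exact by
#'   construction).
#' @return list with `index` (a `harvest_index`) and `expected` (data.frame
#'   of the per-repository ground-truth marginals in
#'   [tabulate_by_repository()] column layout).
#' @export
make_index <- function(profile, seed = 1L) {
  ds_list <- list(); f_list <- list(); exp_list <- list()

  for (p in profile) {
    repo <- p$repository
    n_ds <- as.integer(p$n_datasets)
    stopifnot(n_ds >= 1L)
    loose_counts <- p$loose_ext_counts %||% c(gro = 1)
    in_zip_counts <- p$in_zip_ext_counts %||% numeric(0)
    total_bytes <- p$total_loose_bytes %||% 0
    md_kw <- p$md_keyword %||% TRUE

    ids <- sprintf("%s-d%05d", repo, seq_len(n_ds))
    dates <- as.character(seq(as.Date(p$date_from), as.Date(p$date_to),
                              length.out = n_ds))
    title <- if (md_kw) {
      sprintf("Molecular dynamics simulation dataset %s", ids)
    } else {
      sprintf("Assorted deposition %s", ids)
    }
    ds_list[[repo]] <- data.frame(
      repository = repo, dataset_id = ids, doi = sprintf("10.5072/%s", ids),
      title = title,
      description = if (md_kw) "Trajectories and input files from an MD study."
                    else "Miscellaneous files.",
      created_date = dates, license = "CC-BY-4.0", stringsAsFactors = FALSE
    )

    # loose files, round-robin over datasets
    ext <- rep(names(loose_counts), times = as.integer(loose_counts))
    n_loose <- length(ext)
    sizes <- numeric(n_loose)
    if (n_loose > 0L && total_bytes > 0) {
      base <- floor(total_bytes / n_loose)
      rem <- total_bytes - base * n_loose
      sizes <- rep(base, n_loose)
      if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
    }
    loose <- if (n_loose > 0L) data.frame(
      repository = repo,
      dataset_id = rep(ids, length.out = n_loose),
      file_name = ifelse(ext == "none", sprintf("file%06d", seq_len(n_loose)),
                         sprintf("file%06d.%s", seq_len(n_loose), ext)),
      extension = ext,
      size_bytes = sizes,
      download_url = NA_character_,
      from_zip = FALSE,
      zip_parent = NA_character_,
      stringsAsFactors = FALSE
    ) else empty_files_df()

    # in-zip files, round-robin over the zip archives
    in_ext <- rep(names(in_zip_counts), times = as.integer(in_zip_counts))
    n_in <- length(in_ext)
    inzip <- empty_files_df()
    if (n_in > 0L) {
      zips <- loose[loose$extension == "zip", , drop = FALSE]
      if (nrow(zips) == 0L) {
        stop("make_index: in-zip files requested but no 'zip' archives in ",
             repo, "'s loose_ext_counts", call. = FALSE)
      }
      zi <- rep(seq_len(nrow(zips)), length.out = n_in)
      inzip <- data.frame(
        repository = repo,
        dataset_id = zips$dataset_id[zi],
        file_name = ifelse(in_ext == "none", sprintf("member%06d", seq_len(n_in)),
                           sprintf("member%06d.%s", seq_len(n_in), in_ext)),
        extension = in_ext,
        size_bytes = NA_real_,
        download_url = NA_character_,
        from_zip = TRUE,
        zip_parent = zips$file_name[zi],
        stringsAsFactors = FALSE
      )
    }
    f_list[[repo]] <- rbind(loose, inzip)

    exp_list[[repo]] <- data.frame(
      repository = repo,
      dataset_count = n_ds,
      first_date = as.character(as.Date(p$date_from)),
      last_date = as.character(as.Date(p$date_to)),
      loose_file_count = n_loose,
      total_size_gb = total_bytes / 1e9,
      zip_file_count = as.integer(loose_counts["zip"] %|na|% 0),
      in_zip_file_count = n_in,
      total_file_count = n_loose + n_in,
      stringsAsFactors = FALSE
    )
  }

  datasets <- do.call(rbind, c(list(empty_datasets_df()), unname(ds_list)))
  files <- do.call(rbind, c(list(empty_files_df()), unname(f_list)))
  expected <- do.call(rbind, unname(exp_list))
  rownames(expected) <- NULL
  list(
    index = harvest_index(datasets, files,
                          manifest = list(generator = "make_index", seed = seed)),
    expected = expected
  )
}

#' @noRd
`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Published census of MD depositions in generalist repositories
#'
#' The per-repository statistics of the March-2023 snapshot of MD-related
#' depositions indexed from Zenodo, Figshare and OSF: dataset counts,
#' first/latest deposition dates, loose files, total size (decimal GB), zip
#' archives, files within zips and grand totals. Used as the reference
#' profile for consistency checks of the report layer — a synthetic index
#' built to these marginals must reproduce every printed total exactly.
#'
#' @return data.frame in [tabulate_by_repository()] row layout (without a
#'   totals row).
#' @export
md_census_2023 <- function() {
  data.frame(
    repository = c("zenodo", "figshare", "osf"),
    dataset_count = c(1011L, 913L, 55L),
    first_date = c("2014-11-19", "2012-08-20", "2017-05-24"),
    last_date = c("2023-03-05", "2023-03-03", "2023-02-05"),
    loose_file_count = c(20250L, 3336L, 6146L),
    total_size_gb = c(12851, 736, 495),
    zip_file_count = c(1780L, 590L, 14L),
    in_zip_file_count = c(141304L, 74720L, 0L),
    total_file_count = c(161554L, 78056L, 6146L),
    stringsAsFactors = FALSE
  )
}

#' Synthetic index reproducing the published census marginals
#'
#' Expands [md_census_2023()] into a [make_index()] profile: zip archives
#' carry the `"zip"` extension, the remaining loose files a generic Gromacs
#' mix, and in-zip members a generic data extension. The resulting index
#' has exactly the census's per-repository dataset, file, zip and size
#' marginals.
#'
#' @param seed integer seed forwarded to [make_index()].
#' @return list with `index` and `expected`, as [make_index()].
#' @export
census_index <- function(seed = 1L) {
  census <- md_census_2023()
  profile <- lapply(seq_len(nrow(census)), function(i) {
    row <- census[i, ]
    n_zip <- row$zip_file_count
    n_rest <- row$loose_file_count - n_zip
    loose <- c(zip = n_zip, gro = n_rest %/% 2L, mdp = n_rest - n_rest %/% 2L)
    list(
      repository = row$repository,
      n_datasets = row$dataset_count,
      date_from = row$first_date,
      date_to = row$last_date,
      loose_ext_counts = loose[loose > 0],
      in_zip_ext_counts = if (row$in_zip_file_count > 0L)
        c(dat = row$in_zip_file_count) else numeric(0),
      total_loose_bytes = row$total_size_gb * 1e9,
      md_keyword = TRUE
    )
  })
  make_index(profile, seed = seed)
}
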