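# Shared fixture builders and independent brute-force oracles.

tiny_water_gro <- function() {
  paste(
    "Single TIP3P water",
    "    3",
    "    1SOL     OW    1   0.230   0.628   0.113",
    "    1SOL    HW1    2   0.137   0.626   0.150",
    "    1SOL    HW2    3   0.231   0.589   0.021",
    "   1.86206   1.86206   1.86206",
    sep = "\n"
  )
}

# a small two-repository mock world: 5 datasets, 3 of them MD-related
mock_world <- function() {
  zen <- make_mock_repository(list(
    name = "zenodo-mock", dialect = "zenodo",
    datasets = list(
      list(dataset_id = "z1", title = "Molecular dynamics of a membrane protein",
           description = "Gromacs trajectories", created_date = "2020-05-01",
           files = list(list(name = "run.mdp", size_bytes = 1200),
                        list(name = "notes.txt", size_bytes = 40)),
           zips = list(list(name = "traj.zip", size_bytes = 5e6,
                            entries = c("sim/md1.xtc", "sim/md2.xtc",
                                        "sim/topol.top", "sim/readme.md")))),
      list(dataset_id = "z2", title = "Microscopy images",
           description = "No simulations here", created_date = "2021-01-10",
           files = list(list(name = "cells.tiff", size_bytes = 900))),
      list(dataset_id = "z3", title = "Coarse-grained martini lipid study",
           description = "md simulation inputs", created_date = "2022-07-15",
           files = list(list(name = "bilayer.gro", size_bytes = 64000),
                        list(name = "prod.mdp", size_bytes = 800)))
    )
  ))
  fig <- make_mock_repository(list(
    name = "figshare-mock", dialect = "figshare",
    datasets = list(
      list(dataset_id = "f1", title = "NAMD simulation of a channel",
           description = "trajectory and psf", created_date = "2019-03-03",
           files = list(list(name = "channel.psf", size_bytes = 2e5),
                        list(name = "channel.dcd", size_bytes = 9e8))),
      list(dataset_id = "f2", title = "Survey results",
           description = "spreadsheets", created_date = "2018-11-11",
           files = list(list(name = "answers.xlsx", size_bytes = 1e4)))
    )
  ))
  list(zenodo = zen, figshare = fig)
}

md_world_queries <- function() {
  list(query_spec("mdp"), query_spec("gro"), query_spec("psf"),
       query_spec("xtc", keyword = "molecular dynamics"))
}

# random make_index profile with approximately n_files files
random_profile <- function(seed, n_files = 1000L) {
  set.seed(seed)
  repos <- c("zenodo", "figshare", "osf")
  exts <- c("xtc", "gro", "mdp", "top", "txt", "dat", "png", "none", "pdb", "zip")
  lapply(repos, function(r) {
    n_loose <- max(2L, rpois(1, n_files / 4))
    counts <- table(sample(exts, n_loose, replace = TRUE,
                           prob = c(4, 3, 3, 1, 2, 2, 1, 1, 2, 2)))
    counts <- stats::setNames(as.integer(counts), names(counts))
    n_zip <- if ("zip" %in% names(counts)) counts[["zip"]] else 0L
    in_zip <- if (n_zip > 0L) {
      nz <- rpois(1, n_files / 12)
      if (nz > 0L) {
        t2 <- table(sample(c("xtc", "log", "dat", "jpg"), nz, replace = TRUE))
        stats::setNames(as.integer(t2), names(t2))
      } else numeric(0)
    } else numeric(0)
    list(repository = r, n_datasets = sample(2:12, 1),
         date_from = "2014-01-01", date_to = "2023-03-01",
         loose_ext_counts = counts, in_zip_ext_counts = in_zip,
         total_loose_bytes = sample.int(1e6, 1),
         md_keyword = TRUE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent brute-force recounts over an index (the report oracle) ---
# Deliberately naive: per-file loops, no shared code with the report layer.

brute_repo_rows <- function(index) {
  out <- list()
  for (repo in sort(unique(index$datasets$repository))) {
    n_ds <- 0L; first <- NA_character_; last <- NA_character_
    for (i in seq_len(nrow(index$datasets))) {
      if (index$datasets$repository[i] == repo) {
        n_ds <- n_ds + 1L
        d <- index$datasets$created_date[i]
        if (is.na(first) || d < first) first <- d
        if (is.na(last) || d > last) last <- d
      }
    }
    loose <- 0L; zipn <- 0L; inzip <- 0L; bytes <- 0
    for (i in seq_len(nrow(index$files))) {
      if (index$files$repository[i] != repo) next
      if (index$files$from_zip[i]) {
        inzip <- inzip + 1L
      } else {
        loose <- loose + 1L
        if (!is.na(index$files$size_bytes[i])) bytes <- bytes + index$files$size_bytes[i]
        if (index$files$extension[i] == "zip") zipn <- zipn + 1L
      }
    }
    out[[repo]] <- data.frame(
      repository = repo, dataset_count = n_ds, first_date = first,
      last_date = last, loose_file_count = loose, total_size_gb = bytes / 1e9,
      zip_file_count = zipn, in_zip_file_count = inzip,
      total_file_count = loose + inzip, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, unname(out))
  rownames(df) <- NULL
  df
}

brute_files_per_year <- function(index) {
  acc <- list()
  for (i in seq_len(nrow(index$files))) {
    repo <- index$files$repository[i]; id <- index$files$dataset_id[i]
    hit <- which(index$datasets$repository == repo & index$datasets$dataset_id == id)
    yr <- substr(index$datasets$created_date[hit], 1, 4)
    key <- paste(yr, repo)
    acc[[key]] <- (acc[[key]] %||% 0L) + 1L
  }
  if (length(acc) == 0L) {
    return(data.frame(year = integer(0), repository = character(0),
                      n_files = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(acc), " ", fixed = TRUE)
  df <- data.frame(
    year = as.integer(vapply(parts, `[`, "", 1L)),
    repository = vapply(parts, `[`, "", 2L),
    n_files = as.integer(unlist(acc)), stringsAsFactors = FALSE)
  df <- df[order(df$year, df$repository), , drop = FALSE]
  rownames(df) <- NULL
  df
}

brute_engine_counts <- function(index, rules, keywords) {
  labels <- c("gromacs", "amber", "namd-charmm", "desmond", "unknown")
  counts <- stats::setNames(integer(5), labels)
  for (i in seq_len(nrow(index$files))) {
    repo <- index$files$repository[i]; id <- index$files$dataset_id[i]
    hit <- which(index$datasets$repository == repo & index$datasets$dataset_id == id)
    meta <- paste(index$datasets$title[hit], index$datasets$description[hit])
    kw <- FALSE
    for (k in keywords) if (grepl(k, tolower(meta), fixed = TRUE)) kw <- TRUE
    ext <- index$files$extension[i]
    lab <- "unknown"
    for (j in seq_len(nrow(rules))) {
      if (rules$extension[j] == ext && (!rules$requires_keyword[j] || kw)) {
        lab <- rules$engine[j]
      }
    }
    counts[[lab]] <- counts[[lab]] + 1L
  }
  counts
}

brute_ecdf_at <- function(values, v) sum(values <= v) / length(values)
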