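# The harvest index: one table of dataset records, one table of file
# records, plus a run manifest. This is the central data structure the
# harvester produces and the report layer consumes.

DATASET_COLUMNS <- c("repository", "dataset_id", "doi", "title", "description",
                     "created_date", "license")
FILE_COLUMNS <- c("repository", "dataset_id", "file_name", "extension",
                  "size_bytes", "download_url", "from_zip", "zip_parent")

#' @noRd
empty_datasets_df <- function() {
  data.frame(
    repository = character(0), dataset_id = character(0), doi = character(0),
    title = character(0), description = character(0),
    created_date = character(0), license = character(0),
    stringsAsFactors = FALSE
  )
}

#' @noRd
empty_files_df <- function() {
  data.frame(
    repository = character(0), dataset_id = character(0),
    file_name = character(0), extension = character(0),
    size_bytes = numeric(0), download_url = character(0),
    from_zip = logical(0), zip_parent = character(0),
    stringsAsFactors = FALSE
  )
}

#' Construct a harvest index
#'
#' Bundles a dataset table and a file table with a run manifest, after
#' validating the schema and the invariants every index must satisfy:
#' `(repository, dataset_id)` unique in the dataset table, every file
#' belonging to a dataset present in the dataset table (referential
#' integrity), `from_zip` true exactly when `zip_parent` is set, and
#' extension `"none"` only for dotless names.
#'
#' @param datasets data.frame with columns `repository`, `dataset_id`,
#'   `doi`, `title`, `description`, `created_date` (ISO `YYYY-MM-DD`),
#'   `license`.
#' @param files data.frame with columns `repository`, `dataset_id`,
#'   `file_name`, `extension`, `size_bytes`, `download_url`, `from_zip`,
#'   `zip_parent`.
#' @param manifest a list of run metadata (queries, timestamps, counts).
#' @return an object of class `harvest_index`.
#' @export
harvest_index <- function(datasets = empty_datasets_df(),
                          files = empty_files_df(),
                          manifest = list()) {
  stopifnot(is.data.frame(datasets), is.data.frame(files), is.list(manifest))
  missing_d <- setdiff(DATASET_COLUMNS, names(datasets))
  missing_f <- setdiff(FILE_COLUMNS, names(files))
  if (length(missing_d) > 0L) {
    stop("dataset table lacks columns: ", paste(missing_d, collapse = ", "), call. = FALSE)
  }
  if (length(missing_f) > 0L) {
    stop("file table lacks columns: ", paste(missing_f, collapse = ", "), call. = FALSE)
  }
  datasets <- datasets[DATASET_COLUMNS]
  files <- files[FILE_COLUMNS]
  dkey <- paste(datasets$repository, datasets$dataset_id, sep = "\r")
  if (anyDuplicated(dkey)) {
    stop("duplicate (repository, dataset_id) in dataset table", call. = FALSE)
  }
  fkey <- paste(files$repository, files$dataset_id, sep = "\r")
  orphan <- !(fkey %in% dkey)
  if (any(orphan)) {
    stop(sum(orphan), " file(s) reference datasets absent from the dataset table",
         call. = FALSE)
  }
  if (nrow(files) > 0L) {
    mism <- xor(files$from_zip, !is.na(files$zip_parent))
    if (any(mism)) {
      stop("from_zip must be TRUE exactly when zip_parent is present", call. = FALSE)
    }
  }
  rownames(datasets) <- NULL
  rownames(files) <- NULL
  structure(list(datasets = datasets, files = files, manifest = manifest),
            class = "harvest_index")
}

#' @export
print.harvest_index <- function(x, ...) {
  cat("Harvest index\n")
  cat("  datasets:", nrow(x$datasets), "\n")
  cat("  files:   ", nrow(x$files),
      sprintf(" (%d loose, %d inside zip archives)\n",
              sum(!x$files$from_zip), sum(x$files$from_zip)), sep = "")
  repos <- sort(unique(x$datasets$repository))
  if (length(repos) > 0L) cat("  repositories:", paste(repos, collapse = ", "), "\n")
  invisible(x)
}

#' Write a harvest index to disk
#'
#' Persists the dataset and file tables as Parquet (columnar, when the
#' `arrow` package is available) and always as `.tsv`, plus the manifest as
#' JSON, under one directory.
#'
#' @param index a `harvest_index`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_index <- function(index, dir) {
  stopifnot(inherits(index, "harvest_index"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  export_tsv(index$datasets, file.path(dir, "datasets.tsv"))
  export_tsv(index$files, file.path(dir, "files.tsv"))
  if (requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_parquet(index$datasets, file.path(dir, "datasets.parquet"))
    arrow::write_parquet(index$files, file.path(dir, "files.parquet"))
  }
  jsonlite::write_json(index$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read a harvest index written by [write_index()]
#'
#' Prefers the Parquet tables when present (and `arrow` is installed),
#' falling back to the `.tsv` ones.
#'
#' @param dir directory holding the index files.
#' @return a `harvest_index`.
#' @export
read_index <- function(dir) {
  pq <- file.path(dir, c("datasets.parquet", "files.parquet"))
  if (all(file.exists(pq)) && requireNamespace("arrow", quietly = TRUE)) {
    datasets <- as.data.frame(arrow::read_parquet(pq[1L]))
    files <- as.data.frame(arrow::read_parquet(pq[2L]))
  } else {
    datasets <- utils::read.delim(file.path(dir, "datasets.tsv"),
                                  stringsAsFactors = FALSE, na.strings = "NA")
    files <- utils::read.delim(file.path(dir, "files.tsv"),
                               stringsAsFactors = FALSE, na.strings = "NA")
    for (col in DATASET_COLUMNS) datasets[[col]] <- as.character(datasets[[col]])
    for (col in setdiff(FILE_COLUMNS, c("size_bytes", "from_zip"))) {
      files[[col]] <- as.character(files[[col]])
    }
    files$from_zip <- as.logical(files$from_zip)
    files$size_bytes <- as.numeric(files$size_bytes)
  }
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()
  harvest_index(datasets, files, manifest)
}
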