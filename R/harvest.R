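# The Explore-and-Expand harvesting engine.
#
# Explore: query a repository for datasets holding MD-specific file types,
# optionally corroborated by a keyword over the free-text metadata.
# Expand: index *every* file of each hit dataset (researchers deposit
# coherent project bundles, so a single MD file flags the whole deposition),
# listing zip-archive contents through the repository's preview.
# Clean: drop datasets whose only MD-looking content turned out to be
# false-positive files inside archives - a kept dataset must hold at least
# one file with a trusted MD extension.
#
# Repository adapters are a behaviour contract (search / fetch_dataset /
# fetch_zip_listing) so the whole engine runs against mock back-ends; live
# REST adapters plug into the same contract.

#' Build a query specification
#'
#' A query pairs a file type with an optional keyword, the way repository
#' searches combine `filetype:` terms with free-text phrases.
#'
#' @param file_type extension token (no dot), e.g. `"mdp"`.
#' @param keyword optional phrase to require in the dataset metadata.
#' @return an object of class `query_spec`.
#' @export
query_spec <- function(file_type, keyword = NULL) {
  file_type <- tolower(as.character(file_type))
  if (length(file_type) != 1L || !nzchar(file_type)) {
    stop("file_type must be a single non-empty token", call. = FALSE)
  }
  structure(list(file_type = file_type, keyword = keyword), class = "query_spec")
}

#' @noRd
assert_adapter <- function(adapter) {
  ok <- is.list(adapter) &&
    is.function(adapter$search) &&
    is.function(adapter$fetch_dataset) &&
    is.function(adapter$fetch_zip_listing) &&
    is.character(adapter$name)
  if (!ok) stop("not a repository adapter (need name, search, fetch_dataset, ",
                "fetch_zip_listing)", call. = FALSE)
  invisible(adapter)
}

#' Explore: find candidate datasets for a set of queries
#'
#' Runs every query against the adapter and returns the union of hit
#' dataset ids, deduplicated. A failing query is surfaced as a warning
#' carrying the query, and the partial results of the other queries are
#' retained.
#'
#' @param adapter a repository adapter (see [make_mock_repository()]).
#' @param queries non-empty list of `query_spec` objects.
#' @return character vector of dataset ids (sorted, unique), with the failed
#'   queries (if any) in attribute `"failed_queries"`.
#' @export
explore <- function(adapter, queries) {
  assert_adapter(adapter)
  if (inherits(queries, "query_spec")) queries <- list(queries)
  if (length(queries) == 0L) stop("explore: empty query list", call. = FALSE)
  hits <- character(0)
  failed <- list()
  for (q in queries) {
    stopifnot(inherits(q, "query_spec"))
    ids <- tryCatch(adapter$search(q), error = function(e) {
      warning(sprintf("explore: query (file_type=%s%s) failed on %s: %s",
                      q$file_type,
                      if (is.null(q$keyword)) "" else paste0(", keyword=", sQuote(q$keyword)),
                      adapter$name, conditionMessage(e)), call. = FALSE)
      failed[[length(failed) + 1L]] <<- q
      NULL
    })
    hits <- union(hits, ids)
  }
  out <- sort(hits)
  if (length(failed) > 0L) attr(out, "failed_queries") <- failed
  out
}

#' Expand: index every file of one dataset
#'
#' Fetches the dataset record and all its loose files; for each zip archive
#' among them, the archive's content listing is fetched through the
#' repository preview and appended as in-zip file records. When the
#' repository offers no zip preview (or listing fails), the archive stays
#' indexed as a single file and a warning is recorded.
#'
#' @param adapter a repository adapter.
#' @param dataset_id id of a dataset known to the adapter.
#' @return list with `dataset` (one-row data.frame) and `files` (data.frame
#'   of file records; in-zip entries have `from_zip = TRUE` and carry their
#'   `zip_parent`).
#' @export
expand <- function(adapter, dataset_id) {
  assert_adapter(adapter)
  got <- adapter$fetch_dataset(dataset_id)  # not-found errors propagate
  ds <- got$dataset
  loose <- got$files
  repo <- ds$repository[1L]

  files <- empty_files_df()
  if (!is.null(loose) && nrow(loose) > 0L) {
    files <- data.frame(
      repository = repo,
      dataset_id = dataset_id,
      file_name = loose$file_name,
      extension = file_extension(loose$file_name),
      size_bytes = as.numeric(loose$size_bytes %||% rep(NA_real_, nrow(loose))),
      download_url = as.character(loose$download_url %||% rep(NA_character_, nrow(loose))),
      from_zip = FALSE,
      zip_parent = NA_character_,
      stringsAsFactors = FALSE
    )
  }

  zips <- files$file_name[files$extension == "zip"]
  for (zf in zips) {
    listing <- tryCatch(adapter$fetch_zip_listing(dataset_id, zf),
                        error = function(e) NULL)
    if (is.null(listing) || !isTRUE(listing$supported)) {
      warning(sprintf("expand: no zip listing for %s in %s/%s; archive indexed as a single file",
                      sQuote(zf), repo, dataset_id), call. = FALSE)
      next
    }
    entries <- listing$entries
    if (nrow(entries) > 0L) {
      files <- rbind(files, data.frame(
        repository = repo,
        dataset_id = dataset_id,
        file_name = entries$path,
        extension = file_extension(entries$path),
        size_bytes = as.numeric(entries$size_bytes),
        download_url = NA_character_,
        from_zip = TRUE,
        zip_parent = zf,
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(files) <- NULL
  list(dataset = ds, files = files)
}

#' Clean: drop datasets with no trusted MD file type
#'
#' The Expand phase deliberately over-collects; archives full of unrelated
#' files can drag in whole false-positive datasets. A dataset is kept if
#' and only if at least one of its files — loose or inside a zip — carries
#' an extension from `trusted_types`.
#'
#' Idempotent: cleaning a cleaned index changes nothing.
#'
#' @param index a `harvest_index`.
#' @param trusted_types character vector of extensions
#'   (default [trusted_md_extensions()]).
#' @return the filtered `harvest_index`; the number of removed datasets is
#'   recorded in `manifest$removed_datasets` and attribute
#'   `"removed_datasets"`.
#' @export
clean_datasets <- function(index, trusted_types = trusted_md_extensions()) {
  stopifnot(inherits(index, "harvest_index"))
  trusted_types <- tolower(trusted_types)
  fkey <- paste(index$files$repository, index$files$dataset_id, sep = "\r")
  good_keys <- unique(fkey[index$files$extension %in% trusted_types])
  dkey <- paste(index$datasets$repository, index$datasets$dataset_id, sep = "\r")
  keep <- dkey %in% good_keys
  removed <- sum(!keep)
  manifest <- index$manifest
  manifest$removed_datasets <- removed
  out <- harvest_index(index$datasets[keep, , drop = FALSE],
                       index$files[fkey %in% dkey[keep], , drop = FALSE],
                       manifest)
  attr(out, "removed_datasets") <- removed
  out
}

#' Run the full Explore-and-Expand harvest
#'
#' For each adapter: Explore with all queries, Expand each hit dataset once,
#' then Clean the combined index. Failures of one adapter are isolated — the
#' run continues with the others and the failure is recorded in the
#' manifest. The manifest also records the query list, per-repository
#' counts, a timestamp and the false-positive removal count, so a run can be
#' audited and re-executed.
#'
#' @param adapters one adapter or a list of adapters.
#' @param queries non-empty list of `query_spec` objects.
#' @param trusted_types extensions for the cleaning step.
#' @return a cleaned `harvest_index`.
#' @export
run_harvest <- function(adapters, queries,
                        trusted_types = trusted_md_extensions()) {
  if (!is.null(adapters$search)) adapters <- list(adapters)
  if (length(adapters) == 0L) stop("run_harvest: need at least one adapter", call. = FALSE)

  datasets <- empty_datasets_df()
  files <- empty_files_df()
  failures <- character(0)
  per_repo <- list()

  for (adapter in adapters) {
    res <- tryCatch({
      ids <- explore(adapter, queries)
      fq <- attr(ids, "failed_queries")
      if (!is.null(fq) && length(fq) == length(queries) && length(ids) == 0L) {
        failures <- c(failures,
                      sprintf("%s: all queries failed during explore", adapter$name))
      }
      ds_list <- list(); f_list <- list()
      for (id in ids) {
        ex <- tryCatch(expand(adapter, id), error = function(e) {
          # e.g. dataset deleted between Explore and Expand: log and skip
          warning(sprintf("run_harvest: skipping %s/%s: %s", adapter$name, id,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
        if (!is.null(ex)) {
          ds_list[[length(ds_list) + 1L]] <- ex$dataset
          f_list[[length(f_list) + 1L]] <- ex$files
        }
      }
      list(
        datasets = do.call(rbind, c(list(empty_datasets_df()), ds_list)),
        files = do.call(rbind, c(list(empty_files_df()), f_list))
      )
    }, error = function(e) {
      warning(sprintf("run_harvest: adapter %s failed: %s", adapter$name,
                      conditionMessage(e)), call. = FALSE)
      failures <<- c(failures, sprintf("%s: %s", adapter$name, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      datasets <- rbind(datasets, res$datasets)
      files <- rbind(files, res$files)
      per_repo[[adapter$name]] <- list(datasets = nrow(res$datasets),
                                       files = nrow(res$files))
    }
  }

  manifest <- list(
    queries = lapply(queries, function(q) list(file_type = q$file_type,
                                               keyword = q$keyword)),
    trusted_types = as.character(trusted_types),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    repositories = per_repo,
    adapter_failures = failures
  )
  clean_datasets(harvest_index(datasets, files, manifest), trusted_types)
}

#' Construct a zip-archive content listing
#'
#' @param entries data.frame with columns `path` and `size_bytes` (`NA` when
#'   the preview omits sizes).
#' @param truncated `TRUE` when the listing hit the repository's preview cap.
#' @param supported `FALSE` for repositories offering no zip preview; the
#'   listing is then empty and not truncated.
#' @return an object of class `zip_listing`.
#' @export
zip_listing <- function(entries = data.frame(path = character(0),
                                             size_bytes = numeric(0),
                                             stringsAsFactors = FALSE),
                        truncated = FALSE, supported = TRUE) {
  stopifnot(is.data.frame(entries), all(c("path", "size_bytes") %in% names(entries)))
  if (!supported && (nrow(entries) > 0L || truncated)) {
    stop("an unsupported zip listing must be empty and not truncated", call. = FALSE)
  }
  structure(list(entries = entries, truncated = isTRUE(truncated),
                 supported = isTRUE(supported)),
            class = "zip_listing")
}

# Preview caps per HTML dialect: Zenodo lists at most the first 1,000
# archive members; the Figshare preview is uncapped.
ZIP_PREVIEW_CAPS <- c(zenodo = 1000L, figshare = NA_integer_)

#' Parse a zip-archive preview page
#'
#' Repositories expose the content of deposited zip archives as an HTML
#' preview rather than through their APIs. Two dialects are understood:
#'
#' * `zenodo`: a `<table class="zip-listing">` whose rows hold the member
#'   path in a `<td class="name">` cell and its size in a
#'   `<td class="size">` cell; the preview stops at the first 1,000 members.
#' * `figshare`: a `<ul class="archive-preview">` whose `<li>` items hold
#'   the member path as text and the size in a `data-size` attribute.
#'
#' A listing whose entry count equals the dialect's cap is flagged
#' `truncated` — the archive may hold more files than the preview shows.
#'
#' @param markup HTML text (single string) or a file path.
#' @param dialect `"zenodo"` or `"figshare"`.
#' @return a `zip_listing`. Unparseable markup yields an empty listing and
#'   a warning.
#' @export
parse_zip_preview <- function(markup, dialect = c("zenodo", "figshare")) {
  dialect <- match.arg(dialect)
  if (length(markup) != 1L || !nzchar(markup)) {
    stop("parse_zip_preview: empty markup", call. = FALSE)
  }
  doc <- tryCatch(xml2::read_html(markup), error = function(e) NULL)
  if (is.null(doc)) {
    warning("parse_zip_preview: unparseable markup", call. = FALSE)
    return(zip_listing())
  }

  if (dialect == "zenodo") {
    rows <- xml2::xml_find_all(doc, "//table[contains(@class,'zip-listing')]//tr[td]")
    path <- xml2::xml_text(xml2::xml_find_first(rows, "td[contains(@class,'name')]"))
    size <- xml2::xml_text(xml2::xml_find_first(rows, "td[contains(@class,'size')]"))
  } else {
    items <- xml2::xml_find_all(doc, "//ul[contains(@class,'archive-preview')]/li")
    path <- xml2::xml_text(items)
    size <- xml2::xml_attr(items, "data-size")
  }
  path <- trimws(path)
  keep <- !is.na(path) & nzchar(path)
  path <- path[keep]
  size_bytes <- suppressWarnings(as.numeric(trimws(size[keep])))
  if (length(path) == 0L) {
    warning("parse_zip_preview: no listing entries found", call. = FALSE)
    return(zip_listing())
  }
  cap <- ZIP_PREVIEW_CAPS[[dialect]]
  zip_listing(
    data.frame(path = path, size_bytes = size_bytes, stringsAsFactors = FALSE),
    truncated = !is.na(cap) && length(path) == cap
  )
}
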