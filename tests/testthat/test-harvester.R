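test_that("explore returns the union of per-query hits, deduplicated", {
  w <- mock_world()
  ids <- explore(w$zenodo, list(query_spec("mdp", "gromacs")))
  expect_equal(ids, "z1")
  # two queries hitting the same dataset return it once
  ids2 <- explore(w$zenodo, list(query_spec("mdp"), query_spec("gro")))
  expect_equal(ids2, c("z1", "z3"))
  expect_error(explore(w$zenodo, list()), "empty query list")
})

test_that("a failing query surfaces a warning and keeps partial results", {
  w <- mock_world()
  flaky <- w$zenodo
  real_search <- flaky$search
  flaky$search <- function(query) {
    if (query$file_type == "gro") stop("boom: transport error")
    real_search(query)
  }
  expect_warning(
    ids <- explore(flaky, list(query_spec("mdp"), query_spec("gro"))),
    "boom")
  expect_equal(ids, c("z1", "z3"), ignore_attr = TRUE)
  expect_length(attr(ids, "failed_queries"), 1)
})

test_that("expand indexes loose files plus zip contents with provenance", {
  w <- mock_world()
  ex <- expand(w$zenodo, "z1")
  expect_equal(nrow(ex$files), 3 + 4)
  expect_equal(sum(ex$files$from_zip), 4)
  expect_equal(unique(ex$files$zip_parent[ex$files$from_zip]), "traj.zip")
  expect_setequal(ex$files$extension[ex$files$from_zip], c("xtc", "top", "md"))
  expect_error(expand(w$zenodo, "nope"), "not found")
})

test_that("expand degrades gracefully when the repository has no zip preview", {
  ad <- make_mock_repository(list(
    name = "osf-mock", dialect = NULL,
    datasets = list(list(
      dataset_id = "o1", title = "md simulation bundle",
      description = "gromacs", created_date = "2020-01-01",
      files = list(list(name = "a.gro", size_bytes = 10),
                   list(name = "b.mdp", size_bytes = 20)),
      zips = list(list(name = "all.zip", size_bytes = 1e6,
                       entries = c("x.xtc", "y.xtc")))))))
  expect_warning(ex <- expand(ad, "o1"), "indexed as a single file")
  expect_equal(nrow(ex$files), 3)  # zip stays a single record
  expect_false(any(ex$files$from_zip))
})

test_that("expand handles datasets with zero files", {
  ad <- make_mock_repository(list(
    name = "empty-mock", datasets = list(list(
      dataset_id = "e1", title = "t", description = "d",
      created_date = "2020-01-01", files = list()))))
  ex <- expand(ad, "e1")
  expect_equal(nrow(ex$dataset), 1)
  expect_equal(nrow(ex$files), 0)
})

test_that("cleaning removes datasets with no trusted file type, idempotently", {
  # false positive: the only MD-looking name sits inside a zip of photos,
  # and .log is not a trusted type
  datasets <- data.frame(
    repository = "r", dataset_id = c("good", "fp"), doi = NA_character_,
    title = "t", description = "d", created_date = "2020-01-01",
    license = NA_character_, stringsAsFactors = FALSE)
  files <- data.frame(
    repository = "r",
    dataset_id = c("good", rep("fp", 3)),
    file_name = c("sys.gro", "photos.zip", "hike.jpg", "trip.log"),
    extension = c("gro", "zip", "jpg", "log"),
    size_bytes = 1, download_url = NA_character_,
    from_zip = c(FALSE, FALSE, TRUE, TRUE),
    zip_parent = c(NA, NA, "photos.zip", "photos.zip"),
    stringsAsFactors = FALSE)
  idx <- harvest_index(datasets, files)
  cleaned <- clean_datasets(idx)
  expect_equal(cleaned$datasets$dataset_id, "good")
  expect_equal(attr(cleaned, "removed_datasets"), 1)
  # soundness: every kept dataset retains a trusted extension
  trusted <- trusted_md_extensions()
  for (id in cleaned$datasets$dataset_id) {
    expect_true(any(cleaned$files$extension[cleaned$files$dataset_id == id]
                    %in% trusted))
  }
  twice <- clean_datasets(cleaned)
  expect_equal(twice$datasets, cleaned$datasets)
  expect_equal(twice$files, cleaned$files)
})

test_that("a dataset is kept with all its files if one trusted file exists", {
  datasets <- data.frame(
    repository = "r", dataset_id = "d", doi = NA_character_, title = "t",
    description = "x", created_date = "2020-01-01", license = NA_character_,
    stringsAsFactors = FALSE)
  files <- data.frame(
    repository = "r", dataset_id = "d",
    file_name = c("one.gro", sprintf("junk%02d.txt", 1:50)),
    extension = c("gro", rep("txt", 50)),
    size_bytes = 1, download_url = NA_character_, from_zip = FALSE,
    zip_parent = NA_character_, stringsAsFactors = FALSE)
  cleaned <- clean_datasets(harvest_index(datasets, files))
  expect_equal(nrow(cleaned$files), 51)
})

test_that("cleaning an empty index is a no-op", {
  idx <- clean_datasets(harvest_index())
  expect_equal(nrow(idx$datasets), 0)
  expect_equal(nrow(idx$files), 0)
})

test_that("the full harvest returns exactly the planted MD datasets", {
  w <- mock_world()
  idx <- suppressWarnings(run_harvest(list(w$zenodo, w$figshare),
                                      md_world_queries()))
  expect_setequal(idx$datasets$dataset_id, c("z1", "z3", "f1"))
  # expand-completeness: loose + zip-listing entries, per dataset
  expect_equal(sum(idx$files$dataset_id == "z1"), 3 + 4)
  expect_equal(sum(idx$files$dataset_id == "z3"), 2)
  expect_equal(sum(idx$files$dataset_id == "f1"), 2)
  # referential integrity
  expect_true(all(idx$files$dataset_id %in% idx$datasets$dataset_id))
  # manifest records the run
  expect_length(idx$manifest$queries, 4)
  expect_equal(idx$manifest$repositories$`zenodo-mock`$datasets, 2)
})

test_that("repeated runs on the same backing store are identical", {
  w <- mock_world()
  a <- suppressWarnings(run_harvest(list(w$zenodo), md_world_queries()))
  b <- suppressWarnings(run_harvest(list(w$zenodo), md_world_queries()))
  expect_identical(a$datasets, b$datasets)
  expect_identical(a$files, b$files)
})

test_that("one failing adapter does not take down the run", {
  w <- mock_world()
  broken <- list(name = "broken", dialect = NULL,
                 search = function(query) stop("api down"),
                 fetch_dataset = function(id) stop("api down"),
                 fetch_zip_listing = function(id, f) stop("api down"))
  idx <- suppressWarnings(run_harvest(list(broken, w$figshare),
                                      list(query_spec("psf"))))
  expect_equal(idx$datasets$dataset_id, "f1")
  expect_match(idx$manifest$adapter_failures, "queries failed")
})

test_that("zip previews parse in both dialects", {
  entries <- data.frame(path = sprintf("dir/file%02d.xtc", 1:12),
                        size_bytes = 100 * (1:12), stringsAsFactors = FALSE)
  for (dialect in c("zenodo", "figshare")) {
    listing <- parse_zip_preview(make_zip_preview(entries, dialect), dialect)
    expect_equal(nrow(listing$entries), 12, info = dialect)
    expect_equal(listing$entries$path, entries$path, info = dialect)
    expect_equal(listing$entries$size_bytes, entries$size_bytes, info = dialect)
    expect_false(listing$truncated, info = dialect)
  }
})

test_that("a zenodo preview at exactly the 1,000-entry cap is truncated", {
  paths <- sprintf("deep/path/f%04d.dat", 1:1000)
  listing <- parse_zip_preview(make_zip_preview(paths, "zenodo"), "zenodo")
  expect_equal(nrow(listing$entries), 1000)
  expect_true(listing$truncated)
})

test_that("unparseable markup yields an empty listing plus a warning", {
  expect_warning(listing <- parse_zip_preview("<div>nothing useful</div>", "zenodo"),
                 "no listing entries")
  expect_equal(nrow(listing$entries), 0)
  expect_false(listing$truncated)
  expect_error(parse_zip_preview("", "zenodo"), "empty markup")
})
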