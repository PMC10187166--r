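rules <- load_engine_rules()
keywords <- load_md_keywords()

test_that("repository tabulation has exact column sums and decimal-GB sizes", {
  empty <- tabulate_by_repository(harvest_index())
  expect_equal(empty$dataset_count, 0)
  expect_equal(empty$total_file_count, 0)

  one <- make_index(list(list(
    repository = "zenodo", n_datasets = 1, date_from = "2020-01-01",
    date_to = "2020-01-01", loose_ext_counts = c(gro = 1),
    total_loose_bytes = 1e9)))
  tab <- tabulate_by_repository(one$index)
  expect_equal(tab$total_size_gb[tab$repository == "zenodo"], 1.0)

  mixed <- make_index(random_profile(42, 600))
  tab2 <- tabulate_by_repository(mixed$index)
  tot <- tab2[tab2$repository == "Total", ]
  body <- tab2[tab2$repository != "Total", ]
  for (col in c("dataset_count", "loose_file_count", "zip_file_count",
                "in_zip_file_count", "total_file_count", "total_size_gb")) {
    expect_equal(tot[[col]], sum(body[[col]]), info = col)
  }
  expect_equal(body$total_file_count, body$loose_file_count + body$in_zip_file_count)
})

test_that("files are counted under their dataset's deposition year", {
  datasets <- data.frame(
    repository = "r", dataset_id = c("a", "b", "c"), doi = NA_character_,
    title = "t", description = "d",
    created_date = c("2016-02-01", "2016-09-09", "2020-12-31"),
    license = NA_character_, stringsAsFactors = FALSE)
  files <- data.frame(
    repository = "r",
    dataset_id = c(rep("a", 2), rep("b", 3), rep("c", 5)),
    file_name = sprintf("f%d.gro", 1:10), extension = "gro", size_bytes = 1,
    download_url = NA_character_, from_zip = FALSE, zip_parent = NA_character_,
    stringsAsFactors = FALSE)
  fy <- files_per_year(harvest_index(datasets, files))
  expect_equal(fy$n_files[fy$year == 2016], 5)
  expect_equal(fy$n_files[fy$year == 2020], 5)
  expect_equal(nrow(files_per_year(harvest_index())), 0)

  # an in-zip file counts the same as a loose one (brute-force recount)
  mixed <- make_index(random_profile(7, 400))$index
  expect_equal(files_per_year(mixed), brute_files_per_year(mixed))
})

test_that("engine distribution sums to the file total and matches a recount", {
  prof <- list(list(repository = "zenodo", n_datasets = 2,
                    date_from = "2020-01-01", date_to = "2021-01-01",
                    loose_ext_counts = c(xtc = 10, txt = 5),
                    total_loose_bytes = 100))
  idx <- make_index(prof)$index
  counts <- engine_distribution(idx, rules, keywords)
  expect_equal(unname(counts[["gromacs"]]), 10)
  expect_equal(unname(counts[["unknown"]]), 5)
  expect_equal(sum(counts), nrow(idx$files))
  expect_equal(sum(engine_distribution(harvest_index(), rules, keywords)), 0)

  rnd <- make_index(random_profile(13, 500))$index
  expect_equal(engine_distribution(rnd, rules, keywords),
               brute_engine_counts(rnd, rules, keywords))
})

test_that("the unknown-extension top-n breaks ties lexicographically", {
  prof <- list(list(repository = "r", n_datasets = 1,
                    date_from = "2020-01-01", date_to = "2020-01-01",
                    loose_ext_counts = c(txt = 5, dat = 5, png = 1),
                    total_loose_bytes = 0))
  idx <- make_index(prof)$index
  top2 <- unknown_extension_top(idx, 2, rules, keywords)
  expect_equal(top2$extension, c("dat", "txt"))
  expect_equal(top2$n_files, c(5, 5))
  all_of_them <- unknown_extension_top(idx, 99, rules, keywords)
  expect_equal(nrow(all_of_them), 3)
  expect_equal(nrow(unknown_extension_top(harvest_index(), 5, rules, keywords)), 0)
})

test_that("extension-less files land in the 'none' bucket", {
  prof <- list(list(repository = "r", n_datasets = 1,
                    date_from = "2020-01-01", date_to = "2020-01-01",
                    loose_ext_counts = c(none = 4, gro = 1),
                    total_loose_bytes = 0))
  idx <- make_index(prof)$index
  top <- unknown_extension_top(idx, 5, rules, keywords)
  expect_equal(top$extension, "none")
  expect_equal(top$n_files, 4)
})

test_that("the ecdf is the textbook one on distinct values", {
  e <- ecdf_table(c(1, 2, 2, 4))
  expect_equal(e$value, c(1, 2, 4))
  expect_equal(e$fraction, c(0.25, 0.75, 1.0))
  expect_equal(ecdf_table(7)$fraction, 1.0)
  expect_equal(nrow(ecdf_table(numeric(0))), 0)

  set.seed(99)
  for (rep in 1:100) {
    values <- sample.int(20, sample.int(30, 1), replace = TRUE)
    e <- ecdf_table(values)
    expect_false(is.unsorted(e$fraction))
    expect_equal(e$fraction[nrow(e)], 1.0)
    at <- e$value[sample.int(nrow(e), 1)]
    expect_equal(e$fraction[e$value == at], brute_ecdf_at(values, at))
  }
})

test_that("the thermostat x barostat cross-tab counts pairs and the no-coupling group", {
  mk <- function(tc, pc) summarize_mdp(parse_mdp(paste0(
    if (is.na(tc)) "" else paste0("tcoupl = ", tc, "\n"),
    if (is.na(pc)) "" else paste0("pcoupl = ", pc, "\n"))))
  sums <- list(mk("v-rescale", "parrinello-rahman"),
               mk("v-rescale", "parrinello-rahman"),
               mk("V-rescale", "Parrinello-Rahman"),
               mk(NA, NA))
  tab <- crosstab_thermo_baro(sums)
  expect_equal(unname(tab["v-rescale", "parrinello-rahman"]), 3)
  expect_equal(unname(tab["undefined", "undefined"]), 1)
  expect_equal(attr(tab, "no_coupling"), 1)
  expect_equal(sum(tab), 4)
  # permutation invariance
  tab2 <- crosstab_thermo_baro(rev(sums))
  expect_equal(as.vector(tab2), as.vector(tab))
})

test_that("trajectory share is .xtc + .trr over Gromacs-assigned files", {
  prof <- list(list(repository = "z", n_datasets = 3,
                    date_from = "2019-01-01", date_to = "2022-01-01",
                    loose_ext_counts = c(xtc = 20, trr = 5, gro = 50, png = 9),
                    total_loose_bytes = 10))
  share <- trajectory_share(make_index(prof)$index, rules, keywords)
  expect_equal(share$n_trajectory, 25)
  expect_equal(share$n_gromacs, 75)
  expect_equal(share$percent, 33)  # 33.33 rounds to 33

  all_xtc <- list(list(repository = "z", n_datasets = 1,
                       date_from = "2020-01-01", date_to = "2020-01-01",
                       loose_ext_counts = c(xtc = 7), total_loose_bytes = 0))
  expect_equal(trajectory_share(make_index(all_xtc)$index, rules, keywords)$percent, 100)

  none <- list(list(repository = "z", n_datasets = 1,
                    date_from = "2020-01-01", date_to = "2020-01-01",
                    loose_ext_counts = c(png = 3), total_loose_bytes = 0))
  expect_error(trajectory_share(make_index(none)$index, rules, keywords),
               "no Gromacs")
})

test_that("temperature histograms are left-closed, right-open and conservative", {
  sums <- lapply(c(298, 298, 310), function(t) {
    summarize_mdp(parse_mdp(paste0("ref_t = ", t)))
  })
  h <- temperature_histogram(sums, 2)
  expect_equal(h$count[h$bin_lo == 298], 2)
  expect_equal(h$count[h$bin_lo == 310], 1)
  expect_equal(sum(h$count), 3)
  expect_equal(nrow(temperature_histogram(list(), 2)), 0)
  # boundary: 300 belongs to [300, 302), not [298, 300)
  h2 <- temperature_histogram(list(summarize_mdp(parse_mdp("ref_t = 300"))), 2)
  expect_equal(h2$bin_lo, 300)
})

test_that("the production split honours band edges and excludes non-production", {
  mk <- function(integrator, dt, nsteps) summarize_mdp(parse_mdp(sprintf(
    "integrator = %s\ndt = %s\nnsteps = %s\ntcoupl = v-rescale", integrator, dt, nsteps)))
  sums <- list(
    mk("md", 0.002, 25e6),    # exactly 50 ns, all-atom -> <=50 ns band
    mk("md", 0.002, 100e6),   # 200 ns
    mk("md", 0.02, 100e6),    # 2000 ns, coarse-grain -> >1 us
    mk("sd", 0.02, 75e6),     # 1500 ns, coarse-grain -> >1 us
    mk("steep", 0.002, 100e6) # minimiser: excluded
  )
  split <- production_time_split(sums)
  expect_equal(attr(split, "n_production"), 4)
  expect_equal(unname(split["all-atom", "<=50 ns"]), 1)
  expect_equal(unname(split["all-atom", "50 ns - 1 us"]), 1)
  expect_equal(unname(split["coarse-grain", ">1 us"]), 2)
  expect_equal(sum(split), 4)
})

test_that("search is the identity without predicates and shrinks with them", {
  idx <- make_index(random_profile(21, 300))$index
  everything <- search_index(idx, NULL, list())
  expect_equal(nrow(everything$files), nrow(idx$files))
  expect_equal(sort(everything$datasets$dataset_id), sort(idx$datasets$dataset_id))

  narrowed <- search_index(idx, NULL, list(extension = "gro"))
  expect_true(all(narrowed$files$extension == "gro"))
  expect_lte(nrow(narrowed$files), nrow(everything$files))
  further <- search_index(idx, NULL, list(extension = "gro", repository = "zenodo"))
  expect_lte(nrow(further$files), nrow(narrowed$files))

  # brute-force scan oracle for a conjunctive filter
  manual <- idx$files[idx$files$extension == "gro" &
                        idx$files$repository == "zenodo", , drop = FALSE]
  expect_equal(sort(further$files$file_name), sort(manual$file_name))
})

test_that("text search matches title+description case-insensitively", {
  datasets <- data.frame(
    repository = "r", dataset_id = c("a", "b"), doi = NA_character_,
    title = c("Coarse-grained Martini system", "Atomistic study"),
    description = c("lipids", "CHARMM force field"),
    created_date = "2020-01-01", license = NA_character_,
    stringsAsFactors = FALSE)
  files <- data.frame(
    repository = "r", dataset_id = c("a", "b"),
    file_name = c("a.gro", "b.gro"), extension = "gro", size_bytes = 1,
    download_url = NA_character_, from_zip = FALSE, zip_parent = NA_character_,
    stringsAsFactors = FALSE)
  idx <- harvest_index(datasets, files)
  hit <- search_index(idx, "martini")
  expect_equal(hit$datasets$dataset_id, "a")
  expect_equal(search_index(idx, "charmm")$datasets$dataset_id, "b")
  expect_equal(nrow(search_index(idx, "amber")$datasets), 0)
})

test_that("tsv export round-trips and sanitises embedded tabs", {
  tab <- data.frame(x = c(1L, 2L), name = c("alpha", "beta"),
                    note = c("plain", "has\ttab and\nnewline"),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_tsv(tab, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$x, tab$x)
  expect_equal(back$note[2], "has tab and newline")

  empty <- data.frame(a = character(0), b = integer(0))
  export_tsv(empty, path)
  expect_equal(readLines(path), "a\tb")
})
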