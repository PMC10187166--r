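rules <- load_engine_rules()
lexicon <- load_residue_lexicon()

test_that("engine assignment follows the rule table and keyword gate", {
  expect_equal(assign_engine("xtc", FALSE, rules), "gromacs")
  expect_equal(assign_engine("xtc", TRUE, rules), "gromacs")
  expect_equal(assign_engine("psf", TRUE, rules), "namd-charmm")
  expect_equal(assign_engine("txt", TRUE, rules), "unknown")
  # keyword-gated extensions need corroboration
  expect_equal(assign_engine("top", FALSE, rules), "unknown")
  expect_equal(assign_engine("top", TRUE, rules), "gromacs")
  expect_equal(assign_engine("dcd", c(FALSE, TRUE), rules),
               c("unknown", "namd-charmm"))
})

test_that("no engine is ever returned for an extension outside the table", {
  outside <- c("pdb", "xyz", "csv", "none", "tar", "gz", "doc", "py")
  expect_true(all(assign_engine(outside, TRUE, rules) == "unknown"))
  expect_true(all(assign_engine(outside, FALSE, rules) == "unknown"))
})

test_that("residue categorisation is case-insensitive with an 'other' fallback", {
  expect_equal(categorize_residue("SOL", lexicon), "water_ions")
  expect_equal(categorize_residue("sol", lexicon), "water_ions")
  expect_equal(categorize_residue("POPC", lexicon), "lipid")
  expect_equal(categorize_residue("XYZQ", lexicon), "other")
  expect_equal(categorize_residue(c("ALA", "DA", "GLC", "W"), lexicon),
               c("protein", "nucleic", "glucid", "water_ions"))
  expect_error(categorize_residue("", lexicon), "empty")
})

test_that("system classes are the sorted solute sets, solvent-only and other aside", {
  expect_equal(classify_system(c(protein = 100, water_ions = 900)), "protein")
  expect_equal(classify_system(c(protein = 10, nucleic = 20, water_ions = 0)),
               "nucleic+protein")
  expect_equal(classify_system(c(other = 50)), "other")
  expect_equal(classify_system(c(water_ions = 3)), "water/ions only")
  expect_equal(classify_system(c(water_ions = 3, other = 1)), "other")
})

test_that("the label space over solute subsets has exactly 17 values", {
  solutes <- c("protein", "lipid", "nucleic", "glucid")
  labels <- character(0)
  for (mask in 0:15) {
    present <- solutes[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0]
    counts <- stats::setNames(rep(10, length(present)), present)
    for (extra in list(c(water_ions = 5), c(other = 5), c())) {
      labels <- c(labels, classify_system(c(counts, extra)))
    }
  }
  expect_equal(length(unique(labels)), 15 + 2)
  # permutation invariance
  expect_equal(classify_system(c(lipid = 1, protein = 2)),
               classify_system(c(protein = 2, lipid = 1)))
})

test_that("composition profiling conserves particle counts", {
  fx <- make_gro(c(protein = 500 %/% 8, lipid = 30, water_ions = 2000), seed = 4)
  s <- summarize_composition(parse_gro(fx$text), lexicon)
  expect_equal(sum(s$category_counts), s$n_particles)
  expect_equal(s$system_class, "lipid+protein")

  water <- summarize_composition(parse_gro(tiny_water_gro()), lexicon)
  expect_equal(unname(water$category_counts[["water_ions"]]), 3)
  expect_equal(water$system_class, "water/ions only")

  odd <- make_gro(c(g1 = 5), seed = 5,
                  extra_templates = list(g1 = list(resname = "GRA",
                                                   atom_names = c("C1", "C2"))))
  so <- summarize_composition(parse_gro(odd$text), lexicon)
  expect_equal(unname(so$category_counts[["other"]]), 10)
  expect_equal(so$system_class, "other")
})

test_that("resolution classification is an inclusive 10 fs cutoff and monotone", {
  expect_equal(infer_resolution(0.002), "all-atom")
  expect_equal(infer_resolution(0.01), "coarse-grain")
  expect_equal(infer_resolution(NA), "unknown")
  dts <- sort(stats::runif(50, 0, 0.05))
  labels <- infer_resolution(dts)
  first_cg <- match("coarse-grain", labels)
  if (!is.na(first_cg)) {
    expect_true(all(labels[first_cg:length(labels)] == "coarse-grain"))
  }
})

test_that("run-type labels separate production from minimisation", {
  prod <- summarize_mdp(parse_mdp(
    "integrator = md\ndt = 0.002\nnsteps = 50000000\ntcoupl = v-rescale"))
  expect_equal(infer_run_type(prod), "production")
  expect_equal(infer_run_type(summarize_mdp(parse_mdp("integrator = steep"))),
               "non-production")
  short <- summarize_mdp(parse_mdp(
    "integrator = md\ndt = 0.001\nnsteps = 500000\ntcoupl = v-rescale"))
  expect_equal(short$sim_time_ns, 0.5)
  expect_equal(infer_run_type(short), "unknown")
  # neither thermostat nor barostat: not a production set-up
  uncoupled <- summarize_mdp(parse_mdp("integrator = md\nnsteps = 100"))
  expect_equal(infer_run_type(uncoupled), "non-production")
})

test_that("coupling vocabularies normalise case-insensitively and idempotently", {
  expect_equal(normalize_thermostat("V-rescale"), "v-rescale")
  expect_equal(normalize_thermostat(NA), "undefined")
  expect_equal(normalize_thermostat("my-custom-t"), "unrecognized")
  expect_equal(normalize_barostat("Parrinello-Rahman"), "parrinello-rahman")
  expect_equal(normalize_barostat("C-rescale"), "c-rescale")
  expect_equal(normalize_barostat(NA), "undefined")

  domain <- c("No", "BERENDSEN", "Nose-Hoover", "andersen", "Andersen-massive",
              "V-RESCALE", "weird", NA)
  once_t <- normalize_thermostat(domain)
  expect_identical(normalize_thermostat(once_t), once_t)
  once_b <- normalize_barostat(c("no", "berendsen", "C-RESCALE",
                                 "parrinello-rahman", "MTTK", "x", NA))
  expect_identical(normalize_barostat(once_b), once_b)
})
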