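# mdindexr

Mining and indexing molecular dynamics (MD) simulation files scattered
across generalist data repositories.

MD groups deposit their simulation output — Gromacs trajectories, run
parameters, topologies — in Zenodo, Figshare and the Open Science Framework,
where it is public but practically invisible: free-text metadata is
unreliable, repository search cannot see inside zip archives, and nothing
indexes the quantities practitioners filter on (engine, system composition,
resolution, simulation length, temperature). mdindexr is for anyone who
wants to find, profile or reuse that data: it discovers MD depositions,
indexes every file they contain, parses the Gromacs formats natively, infers
missing metadata with explicit rules, and aggregates everything into corpus
statistics and a searchable, exportable index.

## What it does

* **Explore-and-Expand harvesting** over pluggable repository adapters:
  find datasets by MD-specific file types (optionally corroborated by
  keywords), then index *every* file of each hit dataset, expanding zip
  archives through the repository's HTML content preview (with the
  1,000-entry preview cap handled), and finally drop false-positive
  datasets that hold no trusted MD file type. Mock adapters make the whole
  engine testable offline.
* **Native Gromacs parsers**, header-level and dependency-light:
  fixed-column `.gro` coordinates (particle counts, residue names, box,
  velocities), `.mdp` run parameters (normalised keys, Gromacs defaults,
  expected simulation time `dt × nsteps`), XDR `.xtc` trajectories (frame
  and atom counts without decompressing coordinates, truncation detection),
  and `.log` run logs (Gromacs version, command line).
* **Rule-based inference**: extension → engine assignment
  (Gromacs / AMBER / NAMD-CHARMM / DESMOND / unknown), residue-lexicon
  composition profiling and system classes (`protein`, `lipid+protein`,
  `water/ions only`, ...), all-atom vs coarse-grain from the time step
  (inclusive 10 fs cutoff), production-run labelling (`md`/`sd` integrator
  and > 1 ns), thermostat/barostat vocabulary normalisation. All
  configuration ships as editable YAML under `inst/extdata/`.
* **Reporting and search**: per-repository summary table with exact totals,
  files-per-year, engine distributions, ECDFs, thermostat × barostat
  cross-tabs, temperature histograms, production-time splits by resolution,
  conjunctive keyword/filter search, and sanitised `.tsv` export. Indices
  persist as Parquet + `.tsv` + JSON manifest.
* **Deterministic synthetic generators** for every input format, each
  returning its own ground truth — the basis of the test suite's
  generator/parser round-trip property.

## Worked example

Harvest a mock repository holding one genuine MD deposition (with a zip
archive of trajectories) and one false positive, then summarise it:

```r
library(mdindexr)

ad <- make_mock_repository(list(
  name = "zenodo-mock", dialect = "zenodo",
  datasets = list(
    list(dataset_id = "z1",
         title = "Molecular dynamics of a membrane protein",
         description = "Gromacs trajectories", created_date = "2020-05-01",
         files = list(list(name = "run.mdp", size_bytes = 1200),
                      list(name = "notes.txt", size_bytes = 40)),
         zips = list(list(name = "traj.zip", size_bytes = 5e6,
                          entries = c("sim/md1.xtc", "sim/md2.xtc",
                                      "sim/topol.top", "sim/readme.md")))),
    list(dataset_id = "z2", title = "Microscopy images",
         description = "No simulations", created_date = "2021-01-10",
         files = list(list(name = "cells.tiff", size_bytes = 900))))))

idx <- run_harvest(list(ad), list(query_spec("mdp"),
                                  query_spec("xtc", keyword = "molecular dynamics")))
idx
#> Harvest index
#>   datasets: 1
#>   files:   7 (3 loose, 4 inside zip archives)
#>   repositories: zenodo-mock
```

The microscopy dataset was explored, expanded and then cleaned away (no
trusted MD extension); the surviving deposition contributes its 3 loose
files plus the 4 archive members, with zip provenance recorded. The
per-repository table shows the accounting — loose files, the archive, its
members, and sizes in decimal GB:

```r
tabulate_by_repository(idx)
#>    repository dataset_count first_date  last_date loose_file_count
#> 1 zenodo-mock             1 2020-05-01 2020-05-01                3
#> 2       Total             1       <NA>       <NA>                3
#>   total_size_gb zip_file_count in_zip_file_count total_file_count
#> 1    0.00500124              1                 4                7
#> 2    0.00500124              1                 4                7
```

Parsing a run-parameter file recovers the simulation set-up:

```r
s <- summarize_mdp(parse_mdp(
  "integrator = md\ndt = 0.002\nnsteps = 50000000
   tcoupl = v-rescale\npcoupl = parrinello-rahman\nref-t = 310 310"))
s
#> MD run parameters (.mdp)
#>   integrator: md
#>   dt (ps):    0.002   nsteps: 50000000
#>   sim time:   100 ns
#>   thermostat: v-rescale   barostat: parrinello-rahman
#>   ref_t (K):  310

infer_resolution(s$dt_ps)  # "all-atom"   (dt below the 10 fs cutoff)
infer_run_type(s)          # "production" (md integrator, 100 ns > 1 ns)
```

A 2 fs time step over 5×10⁷ steps is a 100 ns all-atom production run at
310 K with the v-rescale thermostat and Parrinello-Rahman barostat — the
metadata a practitioner needs, none of which was in the dataset's
description.

See `vignettes/mining-md-depositions.Rmd` for the full account of the
harvesting model, the parsing and inference rules, and their design
rationale. A command-line wrapper over the same functions lives at
`inst/scripts/mdindex.R` (subcommands `harvest`, `parse`, `report`,
`search`).

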