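---
title: "Mining molecular dynamics depositions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining molecular dynamics depositions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdindexr)
```

## The problem

Molecular dynamics (MD) groups increasingly deposit simulation output in
generalist data repositories — Zenodo, Figshare, the Open Science Framework —
rather than in a dedicated archive. The files are public but effectively
dark: dataset titles and descriptions are free text of wildly varying
quality, repository search indexes do not reach inside zip archives, and
nothing records the metadata an MD practitioner actually filters on
(engine, system composition, resolution, simulation length, temperature).
mdindexr builds that missing layer: it discovers MD depositions, indexes
every file they contain, parses the Gromacs file formats natively, infers
the missing metadata with explicit rules, and aggregates the result into
corpus statistics and a searchable table.

## Explore and Expand

Plain keyword search over free-text metadata produces many false positives,
because depositors describe their data inconsistently or barely at all.
The harvesting strategy therefore anchors on *file types*, which MD engines
emit with highly specific extensions, and uses keywords only as
corroboration:

1. **Explore** — query a repository for datasets holding a specific
   extension (`.mdp`, `.gro`, `.psf`, ...), optionally in conjunction with an
   MD keyword for extensions too generic to trust alone.
2. **Expand** — for every hit dataset, index *all* of its files, whatever
   their type. The underlying assumption is that a deposition is a coherent
   project bundle: one genuine MD file flags the whole dataset as
   MD-related. Zip archives are expanded through the repository's HTML
   content preview, never by downloading them.
3. **Clean** — the Expand phase deliberately over-collects, and an archive
   match can be a false positive (a `.log` inside a zip of photographs is
   not a Gromacs log). A dataset survives only if at least one of its
   files, loose or in-zip, carries a trusted MD extension.

Repository adapters are a three-function behaviour contract (`search`,
`fetch_dataset`, `fetch_zip_listing`), so the engine itself is agnostic to
where data lives, runs unmodified against the in-memory mock adapters that
the test suite uses, and isolates per-adapter failures: one repository
being down degrades the run instead of aborting it. Zip previews are parsed
from two documented HTML dialects (a table-based one whose listing stops at
1,000 members, and an uncapped list-based one); a listing that exactly fills
the cap is flagged truncated, because the archive may hold more than the
preview shows. Repositories without any preview contribute the archive as a
single indexed file.

## Native Gromacs parsers

Four formats are parsed with no external dependencies, because header-level
metadata is all the pipeline needs and full trajectory decoding would be
wasteful at corpus scale:

* **.gro** — fixed-column coordinate text: 5-character fields for residue
  number, residue name, atom name and atom number, then three 8-character
  position fields (nm); lines longer than 68 characters carry velocities.
  The particle count is always the declared count cross-checked against the
  line count — residue and atom *numbers* wrap above 99,999 in large
  systems and are never used for counting. A count mismatch, an unreadable
  fixed column (reported with its line number), or a box line with neither
  3 nor 9 floats is a hard error.
* **.mdp** — `key = value` text. `;` comments are stripped, keys are
  lowercased with `-` mapped to `_` (Gromacs treats `Tcoupl`, `tcoupl` and
  `ref-t`, `ref_t` as identical), duplicate keys resolve last-wins like the
  Gromacs preprocessor, and values stay verbatim. A line without `=` is a
  recorded warning, never fatal. The expected simulation time is
  `dt × nsteps / 1000` ns, with the Gromacs runtime defaults (`dt` 0.001 ps,
  `nsteps` 0) when keys are absent; a non-numeric value marks the field
  absent with a warning rather than failing, since corpus files contain
  every imaginable typo.
* **.xtc** — XDR binary, big-endian, 4-byte aligned. Each frame's header
  (magic 1995, atom count, step, time) and the compressed coordinate
  block's self-describing layout are read; the advertised byte count,
  rounded up to the 4-byte boundary, is skipped without decompression.
  Systems of at most 9 atoms store plain floats and are skipped
  arithmetically. A wrong magic on the first frame rejects the file as
  not-XTC; a later frame with a different atom count is an inconsistency
  error; a trailing partial frame (including mid-stream garbage, which is
  indistinguishable from truncation without decoding) simply sets a
  `truncated` flag — damaged tails are common in deposited data and must
  not hide the frames that do parse.
* **.log** — two regular expressions recover the Gromacs version (modern
  `GROMACS version:` line or the classic smiley banner) and the `Command
  line:` block. Absent patterns yield absent fields, never empty strings.

All text parsers accept LF and CRLF, and fall back from UTF-8 to latin-1.

## Inference rules

Every inferred label is a deliberately simple, documented rule — the goal
is a transparent, reproducible annotation, not a classifier.

* **Engine assignment** is a pure extension lookup in an editable YAML rule
  table. Extensions unique to an engine (`.xtc`, `.prmtop`, `.psf`, `.cms`,
  ...) always assign; generic ones (`.top`, `.ndx`, `.dcd`, `.inp`, `.crd`,
  `.mae`) require the dataset metadata to match an MD keyword. NAMD and
  CHARMM share a file ecosystem and are one combined label. Anything else
  is `unknown` — the table never guesses.
* **Residue categories.** The `.gro` residue-name column is matched
  case-insensitively against a curated lexicon mapping tokens to protein,
  lipid, nucleic, glucid or water/ions; unknown tokens are `other`. The
  category memberships shipped in `inst/extdata/residue_lexicon.yml` are
  the package's own curation (standard amino acids with protonation
  variants, common DNA/RNA codes, widespread lipid and sugar names, water
  models and counter-ions including the Martini water beads) and are meant
  to be edited — the categories, not the membership, are the contract.
* **System class** is the sorted, `+`-joined set of *solute* categories
  present in the system. Water/ions and `other` never enter the label:
  a solvated protein is `protein`, not `protein+water`. With no recognised
  solute, a system is `water/ions only` when it is water/ions throughout,
  and `other` otherwise. This yields exactly 17 possible labels (15
  non-empty solute subsets plus the two fallbacks), which the tests verify
  by enumeration.
* **Resolution.** Coarse-grained force fields such as Martini integrate
  with time steps an order of magnitude above atomistic ones, so the time
  step is used as a single cutoff: `dt ≥ 0.01` ps (10 fs) labels a set-up
  coarse-grain, below is all-atom, absent is unknown. The cutoff is
  deliberately *inclusive* — 10 fs is the canonical Martini-style value and
  must classify as coarse-grain.
* **Run type.** A production run uses the `md` or `sd` integrator with a
  set-up time above 1 ns. Energy minimisers (`steep`, `cg`, `l-bfgs`) are
  non-production, as are set-ups with neither thermostat nor barostat
  coupling (minimisation, ion placement, MM/PBSA-style rescoring).
  Everything else — short dynamics, exotic integrators — stays `unknown`
  rather than being forced into a bucket.
* **Coupling vocabularies.** Raw `tcoupl`/`pcoupl` tokens normalise
  case-insensitively onto the documented Gromacs value sets (thermostats:
  no, berendsen, nose-hoover, andersen, andersen-massive, v-rescale;
  barostats: no, berendsen, c-rescale, parrinello-rahman, mttk). Absent is
  `undefined`, out-of-vocabulary is `unrecognized`, and both functions are
  idempotent. When several `ref_t` groups are listed, the first value is
  the reported starting temperature (a warning notes differing groups) —
  a corpus analysis wants one temperature per file.

## Reporting conventions

* Sizes are decimal gigabytes (1 GB = 10⁹ bytes), the unit repositories
  themselves display; totals are summed in bytes and converted once, so
  the totals row of the per-repository table is exact integer arithmetic.
* Files are dated by their dataset's deposition date — previews carry no
  per-file dates.
* Simulation-time bands break at exactly 50 ns and 1 μs, with the first
  edge closed on the left band: a 50 ns set-up counts as "≤ 50 ns".
* Temperature histograms use left-closed, right-open bins (default 2 K).
* Rounded percentages use round-half-away-from-zero (base R's `round`
  rounds half to even, which would be surprising in a printed share).
* Top-N extension tables break count ties lexicographically so output is
  deterministic.
* The thermostat × barostat cross-tab reports the `undefined × undefined`
  cell separately as the no-coupling group, since those files are by
  definition not production set-ups.
* Search is conjunctive and case-insensitive, ordered by repository,
  dataset id and file name; `.tsv` export replaces embedded tabs/newlines
  with spaces so files stay rectangular on re-import.

## Synthetic generators

Every input the pipeline consumes can be generated deterministically:
`.gro` files from per-category molecule counts (water 3 atoms, generic
protein residue 8, lipid 50, nucleic 20, glucid 12, plus a free-form
template hook), `.mdp` files in four dialect styles, `.xtc` byte streams
with valid frame scaffolding, mock repository adapters, and whole indices
with exact per-repository marginals. Each generator returns its own ground
truth, and `parse(make_X(spec)) == truth` across randomised seeds is the
core testing property.

What the generators deliberately do **not** emulate: physically meaningful
coordinates (positions are uniform noise in the box), force-field
consistency, real compressed `.xtc` payloads (the coordinate block has the
correct advertised length but arbitrary content — sufficient because the
scanner never decompresses), or the full messiness of real repository
metadata. Passing tests therefore demonstrate format-level and
accounting-level correctness, not robustness to every malformed file in
the wild; the parsers' warning-not-fatal policy is the hedge for the
latter.

Two reference conditions are fixed by published numbers rather than chosen
here: the per-repository census marginals of the March-2023 snapshot
(`md_census_2023()`), which a synthetic index must reproduce through the
report layer exactly, and the Gromacs file-type counts whose trajectory
share is 34%. Test problem sizes elsewhere were chosen once as realistic
desk-scale conditions: 100 random seeds per format for the round-trip
property, mock worlds of a few datasets including a 1,200-member archive
against the 1,000-entry preview cap, and random indices of a few thousand
files (up to 10⁴) for the brute-force aggregation oracles.

## Degenerate inputs and numerical choices

Empty `.mdp` files summarise from defaults; an empty `.xtc` stream is zero
frames, not an error; an empty index aggregates to zeros; cleaning an
empty index is a no-op. `sim_time_ns` is invariant under numeric
representation (`0.002` vs `2e-3`). Extension extraction lowercases the
text after the final dot, maps dotless names to the explicit bucket
`none`, and treats `.tar.gz` as `gz`. Dataset identity is the
(repository, dataset id) pair throughout, and the index constructor
enforces referential integrity, so no aggregation can silently count an
orphaned file.

## Known limitations

* Only the latest version of a deposition is indexed; version histories
  are not walked.
* `.tpr`, `.trr` payloads and topology semantics are out of scope — these
  files are counted and sized, not opened.
* Engine assignment is extension-based by design; a renamed file is
  invisible to it.
* The residue lexicon is finite; exotic residue names land in `other`,
  which slightly inflates that class in composition profiles.
* The run-type rule cannot tell whether a simulation actually ran to its
  configured length — it reports set-up intent, which is the only
  information an `.mdp` file holds.
* Live REST adapters are thin shells over the same contract and are not
  exercised by the test suite; correctness claims are about the engine,
  the parsers and the rules, not about any repository's API stability.
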