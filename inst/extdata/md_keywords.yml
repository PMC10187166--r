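# MD-related keywords matched case-insensitively as substrings over a
# dataset's title + description, used both by Explore queries and by
# keyword-gated engine rules.
keywords:
  - molecular dynamics
  - md simulation
  - gromacs
  - charmm
  - namd
  - amber
  - desmond
  - martini
  - force field
  - trajectory
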