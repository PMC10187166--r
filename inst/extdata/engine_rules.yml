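# File-extension -> MD engine rule table. Extensions unique across engines.
# requires_keyword marks extensions that are too generic to be trusted on
# their own; they are only assigned to the engine when the dataset's
# title+description also matches an MD keyword.
gromacs:
  xtc: false
  gro: false
  mdp: false
  tpr: false
  trr: false
  edr: false
  itp: false
  cpt: false
  g96: false
  top: true
  ndx: true
amber:
  prmtop: false
  parm7: false
  inpcrd: false
  rst7: false
  mdcrd: false
  ncrst: false
namd-charmm:
  psf: false
  prm: false
  rtf: false
  dcd: true
  inp: true
  crd: true
desmond:
  cms: false
  dtr: false
  mae: true
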