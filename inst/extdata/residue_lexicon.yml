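# Residue-name lexicon used to profile molecular systems from .gro files.
# Categories are fixed (protein, lipid, nucleic, glucid, water_ions);
# membership is curated and editable. Lookup is case-insensitive; residue
# names not listed here fall into the implicit "other" category.
protein:
  - ALA
  - ARG
  - ASN
  - ASP
  - CYS
  - GLN
  - GLU
  - GLY
  - HIS
  - ILE
  - LEU
  - LYS
  - MET
  - PHE
  - PRO
  - SER
  - THR
  - TRP
  - TYR
  - VAL
  # protonation / tautomer variants (AMBER + CHARMM naming)
  - HID
  - HIE
  - HIP
  - HSD
  - HSE
  - HSP
  - CYX
  - CYM
  - LYN
  - ASH
  - GLH
  # capping groups and modified residues
  - ACE
  - NME
  - NH2
  - MSE
nucleic:
  - DA
  - DC
  - DG
  - DT
  - DA5
  - DA3
  - DC5
  - DC3
  - DG5
  - DG3
  - DT5
  - DT3
  - A
  - C
  - G
  - U
  - RA
  - RC
  - RG
  - RU
  - A5
  - A3
  - C5
  - C3
  - G5
  - G3
  - U5
  - U3
lipid:
  - POPC
  - POPE
  - POPG
  - POPS
  - POPA
  - DPPC
  - DPPE
  - DPPG
  - DOPC
  - DOPE
  - DOPS
  - DLPC
  - DMPC
  - DSPC
  - DOPG
  - CHOL
  - CHL1
  - PSM
  - SSM
  - CDL1
  - CDL2
  - POP2
  - PIP2
  - TOCL
  - LPPC
glucid:
  - GLC
  - BGLC
  - AGLC
  - BGC
  - GAL
  - BGAL
  - MAN
  - BMAN
  - NAG
  - NDG
  - FUC
  - SIA
  - XYL
  - GLA
  - SUC
  - TRE
water_ions:
  - SOL
  - WAT
  - HOH
  - TIP3
  - TIP4
  - TIP5
  - T3P
  - T4P
  - SPC
  - SPCE
  - "NA"
  - "NA+"
  - SOD
  - CL
  - CL-
  - CLA
  - K
  - K+
  - POT
  - MG
  - MG2
  - CA
  - CA2
  - CAL
  - ZN
  - ION
  - NH4
  # Martini water beads (regular, antifreeze, polarizable)
  - W
  - WF
  - PW
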