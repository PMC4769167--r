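Deposited crystal structures are not redistributed with this package.

To run the structure-based acceptance checks, download the following
entries from the Protein Data Bank (https://www.rcsb.org) and place them
in this directory before installing:

  1OTS.pdb   ClC-ec1 wild type (occluded state, bound Cl-)
  1OTU.pdb   ClC-ec1 E148Q (outward-facing occluded mimic; optional)
  5HD8.pdb   ClC-ec1 D417C, inter-subunit disulfide cross-linked
  3DET.pdb   ClC-ec1 E148A/Y445A (channel-like variant)
  1KPL.pdb   Salmonella CLC homolog (optional, cross-homolog comparison)

Everything else in the test suite and the acceptance script runs without
these files, on synthetic structures generated in code.
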