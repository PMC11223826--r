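Place local copies of the PDB entries used by the accession-anchored
worked examples here, as uncompressed PDB files:

  4MR8.pdb  (GABA-B receptor extracellular heterodimer, inactive)
  4MS3.pdb  (GABA-B receptor extracellular heterodimer, agonist-bound)
  3BEP.pdb  (bacterial DNA sliding clamp bound to primed DNA)

They are not redistributed with the package.  With the files in place,
accessionAnchoredChecks() and the corresponding acceptance test compare
the heterodimer interface areas (about 700 vs about 1400 A^2) and the
DNA-contacting clamp residues (R24 in both subunits, Q149 in one).
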