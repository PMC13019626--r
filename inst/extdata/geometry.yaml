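# Ideal peptide geometry used by the internal-coordinate builder.
# Bond lengths in Angstrom, angles in degrees. Editable; any
# self-consistent set works for protocol testing.
bond_lengths:
  N-CA: 1.458
  CA-C: 1.525
  C-N: 1.329
  C-O: 1.231
  N-H: 1.010
  CA-CB: 1.521
  CH3-C: 1.508
  N-CH3: 1.455
bond_angles:
  CA-C-N: 116.2
  C-N-CA: 121.7
  N-CA-C: 111.2
  CA-C-O: 120.1
  C-N-H: 119.2
  N-CA-CB: 110.4
  CH3-C-N: 116.2
  C-N-CH3: 121.7
  CH3-C-O: 120.4
torsion_offsets:
  # torsion(C_prev, N, CA, CB) = phi + cb; fixed L-chirality convention
  cb: -122.6
  # carbonyl O anti to the next N: torsion(N, CA, C, O) = psi + o
  o: 180.0
  # amide H anti to CA across the peptide bond: torsion = omega + h
  h: 180.0
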