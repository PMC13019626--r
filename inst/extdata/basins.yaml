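# Ramachandran basin model for the synthetic coil-library generator.
# phi/psi are basin centres (degrees), sd a circular standard deviation,
# weight the basin probability (normalised per residue class). These are
# coil-like propensities chosen for conformational diversity; they make no
# claim about any force field.
default:
  - {name: ppii,   phi:  -75, psi: 145, sd: 20, weight: 0.45}
  - {name: beta,   phi: -135, psi: 145, sd: 20, weight: 0.25}
  - {name: alphaR, phi:  -65, psi: -45, sd: 12, weight: 0.25}
  - {name: alphaL, phi:   55, psi:  45, sd: 12, weight: 0.05}
glycine:
  - {name: ppii,   phi:  -80, psi: 150, sd: 25, weight: 0.30}
  - {name: beta,   phi: -150, psi: 160, sd: 25, weight: 0.20}
  - {name: alphaR, phi:  -65, psi: -40, sd: 15, weight: 0.25}
  - {name: alphaL, phi:   70, psi:  30, sd: 15, weight: 0.25}
proline:
  - {name: ppii,   phi:  -65, psi: 150, sd:  8, weight: 0.70}
  - {name: alphaR, phi:  -65, psi: -30, sd:  8, weight: 0.30}
preproline:
  - {name: ppii,   phi:  -75, psi: 145, sd: 20, weight: 0.55}
  - {name: beta,   phi: -135, psi: 145, sd: 20, weight: 0.30}
  - {name: alphaR, phi:  -65, psi: -45, sd: 12, weight: 0.15}
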