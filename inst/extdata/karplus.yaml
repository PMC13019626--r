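# Karplus parameter sets for 3J(HN-HA): J = A cos^2(phi + delta)
#                                           + B cos(phi + delta) + C  [Hz]
# Three literature sets; coefficients are configuration, editable.
sets:
  - {name: pardi,       A: 6.40, B: -1.40, C: 1.90, delta: -60}
  - {name: vuister_bax, A: 6.51, B: -1.76, C: 1.60, delta: -60}
  - {name: hu_bax,      A: 7.09, B: -1.42, C: 1.55, delta: -60}
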