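# Synthetic stand-in for the TraR reference used for residue numbering.
# The sequence is a deterministic construction (not the biological TraR)
# carrying the expected residues at the numbered invariant sites; the
# analysis only consumes the numbering and the expected residues.
reference_id: TraR
sequence: >-
  GFKNGHPGHDTMSRSHNDLYMMIFHMQCRYKLPECYQHVQCEARPQYEYEQEPQPSWNNF
  YDPKAPTCTDPWWMNESDHFCYMEWGTGPNHGRNVNCVPQHKRILPLSKTNLCIVSWVRV
  EMPCTPTQGRRIKCFELHWKPAHNHVMKPGILAKAIWWQEAMHWGNPKINQMHNVIFEEG
  SLAKQLEGTWNMPWHWQNRQNLKYPVINCWWHSIYRDTNAIHPCFDYHNRDESL
sites:
  - {position: 57,  expected: "W", role: autoinducer_binding}
  - {position: 61,  expected: "Y", role: autoinducer_binding}
  - {position: 70,  expected: "D", role: autoinducer_binding}
  - {position: 85,  expected: "W", role: autoinducer_binding}
  - {position: 178, expected: "E", role: DNA_binding}
  - {position: 182, expected: "L", role: DNA_binding}
  - {position: 188, expected: "G", role: DNA_binding}
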