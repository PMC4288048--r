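# Synthetic stand-in for the TraI reference used for synthase residue
# numbering.  The ten residues required for AHL synthase activity are
# defined in the structural literature; transcribe them here as
#   - {position: <n>, expected: "<residue>" (quoted), role: synthase_active}
# before running synthase-site reports.  The site list ships empty.
reference_id: TraI
sequence: >-
  RHEGMRCYKMDNAPTVGRALLAFKLHTRFRGAQMLQSEYDLWMVRNALGQYGKSAGYALI
  NIEIVEVKPNHICCINTETGNCVWGLPPEVVRRECYWRHHAPQLELELLMYFYYVPDWRQ
  KWIMLWWNYDAEVIKAKDQSHAKEWERIKGGILQQEARHARQDVQLGEEPRWLNAKHNMS
  WIKYCPPQLWDSFYWTKHEKQHTLSCYRHHR
sites: []
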