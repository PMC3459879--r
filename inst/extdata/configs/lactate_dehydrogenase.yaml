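# L-lactate dehydrogenase: representative open (apo) / closed (liganded) pair.
# Structures are fetched by accession into the local cache on first use.
name: lactate_dehydrogenase
structures:
  - id: 3d0o
    accession: 3d0o
    role: open
  - id: 3d4p
    accession: 3d4p
    role: closed
representative_open: 3d0o
representative_closed: 3d4p
loop:
  chain: A
  start: 81
  end: 91
anm:
  cutoff: 15.0
  gamma: 1.0
  n_soft_modes: 10
random:
  n_sets: 100
  seed: 1
weighting: amplitude_inv_eig
ligand_strip: true
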