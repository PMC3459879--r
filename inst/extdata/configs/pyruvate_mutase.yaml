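# Pyruvate (phosphoenolpyruvate) mutase: representative open (apo) / closed (liganded) pair.
# Structures are fetched by accession into the local cache on first use.
name: pyruvate_mutase
structures:
  - id: 1s2t
    accession: 1s2t
    role: open
  - id: 1m1b
    accession: 1m1b
    role: closed
representative_open: 1s2t
representative_closed: 1m1b
loop:
  chain: A
  start: 118
  end: 134
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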