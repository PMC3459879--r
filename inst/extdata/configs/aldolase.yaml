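# Bisphosphate aldolase: representative open (apo) / closed (liganded) pair.
# Structures are fetched by accession into the local cache on first use.
name: aldolase
structures:
  - id: 3c4u
    accession: 3c4u
    role: open
  - id: 3c52
    accession: 3c52
    role: closed
representative_open: 3c4u
representative_closed: 3c52
loop:
  chain: A
  start: 176
  end: 191
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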