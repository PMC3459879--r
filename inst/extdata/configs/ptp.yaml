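# Protein tyrosine phosphatase (Yersinia): representative open (apo) / closed (liganded) pair.
# Structures are fetched by accession into the local cache on first use.
name: ptp
structures:
  - id: 1ypt
    accession: 1ypt
    role: open
  - id: 1yts
    accession: 1yts
    role: closed
representative_open: 1ypt
representative_closed: 1yts
loop:
  chain: A
  start: 352
  end: 361
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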