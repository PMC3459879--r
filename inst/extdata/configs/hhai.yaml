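# HhaI methyltransferase: representative open (apo) / closed (liganded) pair.
# Structures are fetched by accession into the local cache on first use.
name: hhai
structures:
  - id: 2hmy
    accession: 2hmy
    role: open
  - id: 3hmt
    accession: 3hmt
    role: closed
representative_open: 2hmy
representative_closed: 3hmt
loop:
  chain: A
  start: 80
  end: 100
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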