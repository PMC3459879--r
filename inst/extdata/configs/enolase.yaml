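# Enolase: representative open (apo) / closed (liganded) pair.
# Structures are fetched by accession into the local cache on first use.
name: enolase
structures:
  - id: 3enl
    accession: 3enl
    role: open
  - id: 7enl
    accession: 7enl
    role: closed
representative_open: 3enl
representative_closed: 7enl
loop:
  chain: A
  start: 34
  end: 50
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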