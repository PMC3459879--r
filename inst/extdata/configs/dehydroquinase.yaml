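# 3-dehydroquinase: representative open (apo) / closed (liganded) pair.
# Structures are fetched by accession into the local cache on first use.
name: dehydroquinase
structures:
  - id: 1gqn
    accession: 1gqn
    role: open
  - id: 1l9w
    accession: 1l9w
    role: closed
representative_open: 1gqn
representative_closed: 1l9w
loop:
  chain: A
  start: 227
  end: 239
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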