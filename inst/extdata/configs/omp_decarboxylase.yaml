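# OMP decarboxylase: representative open (apo) / closed (liganded) pair.
# Structures are fetched by accession into the local cache on first use.
name: omp_decarboxylase
structures:
  - id: 3gdk
    accession: 3gdk
    role: open
  - id: 3gdl
    accession: 3gdl
    role: closed
representative_open: 3gdk
representative_closed: 3gdl
loop:
  chain: A
  start: 203
  end: 218
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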