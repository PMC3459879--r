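# Triosephosphate isomerase (chicken): representative open (apo) / closed (liganded) pair.
# Structures are fetched by accession into the local cache on first use.
name: tim
structures:
  - id: 8tim
    accession: 8tim
    role: open
  - id: 1tph
    accession: 1tph
    role: closed
representative_open: 8tim
representative_closed: 1tph
loop:
  chain: A
  start: 166
  end: 176
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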