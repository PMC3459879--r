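# beta-1,4-galactosyltransferase: representative open (apo) / closed (liganded) pair.
# Structures are fetched by accession into the local cache on first use.
name: b14_galactosyltransferase
structures:
  - id: 1fgx
    accession: 1fgx
    role: open
  - id: 1nkh
    accession: 1nkh
    role: closed
representative_open: 1fgx
representative_closed: 1nkh
loop:
  chain: A
  start: 345
  end: 365
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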