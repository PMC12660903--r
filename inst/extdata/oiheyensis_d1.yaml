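# Subdomain registry for the O. iheyensis group II intron D1 scaffold.
# Residue numbers are author (intron) numbering on a single chain.
subdomains:
  - name: core_d1c
    chain: A
    ranges: [[66, 75], [112, 121]]
  - name: peripheral_d1c
    chain: A
    ranges: [[80, 102]]
  - name: d1d1
    chain: A
    ranges: [[124, 133], [230, 242]]
  - name: i1_i2
    chain: A
    ranges: [[6, 23], [250, 267]]
gate:
  - {chain: A, resno: 75, atom: "C1'"}
  - {chain: A, resno: 238, atom: "C1'"}
angles:
  - {name: A, between: [core_d1c, d1d1]}
  - {name: B, between: [core_d1c, peripheral_d1c]}
  - {name: C, between: [core_d1c, i1_i2]}
  - {name: D, between: [d1d1, i1_i2]}
hinges:
  # Two hinge-1 variants circulate in the source literature (115-116 from the
  # structural comparison, 114-116 from the mutagenesis design). Both are
  # recorded; analyses that exclude hinge residues use the union.
  hinge1: [[71, 73], [115, 116]]
  hinge1_mutagenesis_variant: [[71, 73], [114, 116]]
  hinge2: [[217, 217], [223, 224]]
atom_set: ["P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'"]
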