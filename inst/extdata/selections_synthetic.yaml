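# Tracked-atom selections for the synthetic generator's pseudo-atom naming.
# Protein probes: the residue atoms tracked for lipid contacts.
# Lipid probes: one headgroup pseudo-atom per lipid molecule.
# Reference groups: depth reference atom and the headgroup set used for
# leaflet assignment / the membrane midplane.
groups:
  # lysine side-chain amine nitrogens (headgroup engagement probes)
  - name: K256_NZ
    role: protein_probe
    atoms:
      - {residue_seq: 256, atom_name: "NZ"}
  - name: K260_NZ
    role: protein_probe
    atoms:
      - {residue_seq: 260, atom_name: "NZ"}
  - name: K271_NZ
    role: protein_probe
    atoms:
      - {residue_seq: 271, atom_name: "NZ"}
  - name: K275_NZ
    role: protein_probe
    atoms:
      - {residue_seq: 275, atom_name: "NZ"}
  # backbone amide nitrogen of L250 (cholesterol hydrogen-bond donor)
  - name: L250_N
    role: protein_probe
    atoms:
      - {residue_seq: 250, atom_name: "N"}
  # indole nitrogen of W252
  - name: W252_NE1
    role: protein_probe
    atoms:
      - {residue_seq: 252, atom_name: "NE1"}
  # S240: side-chain oxygen or amide nitrogen -> track both, min distance
  - name: S240
    role: protein_probe
    atoms:
      - {residue_seq: 240, atom_name: "OG"}
      - {residue_seq: 240, atom_name: "N"}
  # P241: backbone carbonyl oxygen or amide nitrogen
  - name: P241
    role: protein_probe
    atoms:
      - {residue_seq: 241, atom_name: "O"}
      - {residue_seq: 241, atom_name: "N"}

  # lipid headgroup pseudo-atoms by class
  - name: PS
    role: lipid_probe
    atoms:
      - {lipid_class: PS, atom_name: "P"}
  - name: PE
    role: lipid_probe
    atoms:
      - {lipid_class: PE, atom_name: "P"}
  - name: PC
    role: lipid_probe
    atoms:
      - {lipid_class: PC, atom_name: "P"}
  - name: PIP
    role: lipid_probe
    atoms:
      - {lipid_class: PIP, atom_name: "P"}
  - name: PA
    role: lipid_probe
    atoms:
      - {lipid_class: PA, atom_name: "P"}
  - name: CHOL
    role: lipid_probe
    atoms:
      - {lipid_class: CHOL, atom_name: "O3"}
  - name: CER
    role: lipid_probe
    atoms:
      - {lipid_class: CER, atom_name: "O1"}

  # depth reference: Calpha of the binding-loop glycine
  - name: G253_CA
    role: reference
    atoms:
      - {residue_seq: 253, atom_name: "CA"}
  # all lipid headgroup atoms (leaflet assignment, midplane)
  - name: headgroups
    role: reference
    atoms:
      - {lipid_class: PS, atom_name: "P"}
      - {lipid_class: PE, atom_name: "P"}
      - {lipid_class: PC, atom_name: "P"}
      - {lipid_class: PIP, atom_name: "P"}
      - {lipid_class: PA, atom_name: "P"}
      - {lipid_class: CHOL, atom_name: "O3"}
      - {lipid_class: CER, atom_name: "O1"}
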