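# Tracked-atom selections for CHARMM36 all-atom systems of the C1b-domain
# construct in a heterogeneous bilayer.
#
# Protein probes (chemical description -> CHARMM36 token):
#   side-chain amine nitrogen of K256/K260/K271/K275  -> NZ
#   backbone amide nitrogen of L250                    -> N
#   indole nitrogen of W252                            -> NE1
#   side-chain oxygen or amide nitrogen of S240        -> OG, N (min over set)
#   backbone carbonyl oxygen or amide nitrogen of P241 -> O, N (min over set)
#
# Lipid probes (chemical description -> CHARMM36 tokens):
#   PS phosphate oxygens and serine carboxylate oxygens
#   PE / PC / PIP / PA phosphate oxygens
#   ceramide hydroxyl oxygens
#   cholesterol hydroxyl oxygen -> O3
#
# Atom naming differs between CHARMM36 releases (notably the PS
# carboxylate and PIP monoester phosphates); override this file when your
# topology uses different tokens.
groups:
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
  - name: L250_N
    role: protein_probe
    atoms:
      - {residue_seq: 250, atom_name: "N"}
  - name: W252_NE1
    role: protein_probe
    atoms:
      - {residue_seq: 252, atom_name: "NE1"}
  - name: S240
    role: protein_probe
    atoms:
      - {residue_seq: 240, atom_name: "OG"}
      - {residue_seq: 240, atom_name: "N"}
  - name: P241
    role: protein_probe
    atoms:
      - {residue_seq: 241, atom_name: "O"}
      - {residue_seq: 241, atom_name: "N"}

  - name: PS
    role: lipid_probe
    atoms:
      - {lipid_class: PS, atom_name: "P"}
      - {lipid_class: PS, atom_name: "O11"}
      - {lipid_class: PS, atom_name: "O12"}
      - {lipid_class: PS, atom_name: "O13"}
      - {lipid_class: PS, atom_name: "O14"}
      - {lipid_class: PS, atom_name: "O13A"}
      - {lipid_class: PS, atom_name: "O13B"}
  - name: PE
    role: lipid_probe
    atoms:
      - {lipid_class: PE, atom_name: "P"}
      - {lipid_class: PE, atom_name: "O11"}
      - {lipid_class: PE, atom_name: "O12"}
      - {lipid_class: PE, atom_name: "O13"}
      - {lipid_class: PE, atom_name: "O14"}
  - name: PC
    role: lipid_probe
    atoms:
      - {lipid_class: PC, atom_name: "P"}
      - {lipid_class: PC, atom_name: "O11"}
      - {lipid_class: PC, atom_name: "O12"}
      - {lipid_class: PC, atom_name: "O13"}
      - {lipid_class: PC, atom_name: "O14"}
  - name: PIP
    role: lipid_probe
    atoms:
      - {lipid_class: PIP, atom_name: "P"}
      - {lipid_class: PIP, atom_name: "O11"}
      - {lipid_class: PIP, atom_name: "O12"}
      - {lipid_class: PIP, atom_name: "O13"}
      - {lipid_class: PIP, atom_name: "O14"}
  - name: PA
    role: lipid_probe
    atoms:
      - {lipid_class: PA, atom_name: "P"}
      - {lipid_class: PA, atom_name: "O11"}
      - {lipid_class: PA, atom_name: "O12"}
      - {lipid_class: PA, atom_name: "O13"}
      - {lipid_class: PA, atom_name: "O14"}
  - name: CHOL
    role: lipid_probe
    atoms:
      - {lipid_class: CHOL, atom_name: "O3"}
  - name: CER
    role: lipid_probe
    atoms:
      - {lipid_class: CER, atom_name: "O1"}

  - name: G253_CA
    role: reference
    atoms:
      - {residue_seq: 253, atom_name: "CA"}
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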