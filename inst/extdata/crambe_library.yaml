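# Guanidine-alkaloid library for Crambe crambe dereplication.
#
# Crambescin homologous series are parametric: the lower guanidinoalkyl
# chain carries (m + 2) methylenes and the upper alkyl chain (n + 2)
# methylenes.  For the chain-parameterised families the carbon count is
# k = k_base + m + n; for the "3"-type families (fixed, unsaturated upper
# chain) it is k = k_base + m.  Hydrogens are 2k + h_offset.  New scaffolds
# can be added here without code changes.
series:
  A:          {k_base: 14, chains: both,  h_offset: -4,  n_atoms: 6, o_atoms: 2}
  didehydroA: {k_base: 14, chains: both,  h_offset: -6,  n_atoms: 6, o_atoms: 2}
  B:          {k_base: 14, chains: both,  h_offset: -2,  n_atoms: 6, o_atoms: 3}
  C:          {k_base: 14, chains: both,  h_offset: -2,  n_atoms: 6, o_atoms: 3}
  A3:         {k_base: 26, chains: lower, h_offset: -12, n_atoms: 6, o_atoms: 2}
  B3:         {k_base: 26, chains: lower, h_offset: -10, n_atoms: 6, o_atoms: 3}
  C3:         {k_base: 26, chains: lower, h_offset: -10, n_atoms: 6, o_atoms: 3}

# Default enumeration ranges; cover all reported assignments with margin.
ranges:
  m: [2, 8]
  "n": [2, 12]

# NOTE: the A-family "core/ester cleavage" ion C(n+10)H(2n+14)NO is
# generalised from only two observed assignments and is provisional; it
# carries the lowest diagnostic weight in the rule set.

# Crambescidins are a closed list (no homologue rule is known), named by
# nominal molecular weight.  known: false marks analogues reported for the
# first time in this dataset.
crambescidins:
  - {name: "crambescidin 800 or isocrambescidin 800", formula: C45H80N6O6, known: true}
  - {name: "crambescidin 816", formula: C45H80N6O7, known: true}
  - {name: "crambescidin 830", formula: C46H82N6O7, known: true}
  - {name: "crambescidin 834", formula: C45H82N6O8, known: false}
  - {name: "crambescidin 841", formula: C44H85N6O9, known: false}
  - {name: "crambescidin 857", formula: C44H85N6O10, known: false}
  - {name: "crambescidin 875", formula: C44H87N6O11, known: false}
  - {name: "crambescidin acid", formula: C22H33N3O4, known: true, markers: false}

# Small guanidine entries: minor crambescins and guanidine-related
# compounds observed as singly charged ions; annotated by formula only.
small_guanidines:
  - {name: "crambescin 253", formula: C14H27N3O, known: true}
  - {name: "crambescin 281", formula: C16H31N3O, known: true}
  - {name: "guanidine-related compound (C14H23N3O3)", formula: C14H23N3O3, known: false}
  - {name: "guanidine-related compound (C14H21N3O2)", formula: C14H21N3O2, known: false}
  - {name: "guanidine-related compound (C15H25N3O3)", formula: C15H25N3O3, known: false}

# Spiked internal standards ([M+H]+ QC anchors).
standards:
  - {name: "Yohimbine", formula: C21H26N2O3, rt: 9.80}
  - {name: "Reserpine", formula: C33H40N2O9, rt: 12.59}
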