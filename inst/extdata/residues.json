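{
  "comment": "Residue elemental formulas and atomic masses used by the mass engine. Each residue formula is the 5'-monophosphate free acid (nucleoside 5'-monophosphate or abasic deoxyribose analog); an oligonucleotide of n residues with 5'-phosphate/3'-OH ends is the sum of residue formulas minus (n-1) H2O. AP: 2-deoxyribose-5-phosphate (closed-ring abasic site). rAP: NaBH4-reduced, ring-opened 2-deoxyribitol-5-phosphate (AP + H2). F: tetrahydrofuran abasic analog (1',2'-dideoxyribose-5-phosphate, AP - O). heavy_substitution lists, per labelable residue, how many C are replaced by 13C and N by 15N under full isotopic substitution.",
  "atomic_masses": {
    "C":   {"monoisotopic": 12.0,          "average": 12.0107},
    "H":   {"monoisotopic": 1.00782503207, "average": 1.00794},
    "N":   {"monoisotopic": 14.0030740048, "average": 14.0067},
    "O":   {"monoisotopic": 15.99491461956,"average": 15.9994},
    "P":   {"monoisotopic": 30.97376163,   "average": 30.973762},
    "C13": {"monoisotopic": 13.0033548378, "average": 13.0033548378},
    "N15": {"monoisotopic": 15.0001088982, "average": 15.0001088982}
  },
  "residues": {
    "A":   {"C": 10, "H": 14, "N": 5, "O": 6, "P": 1},
    "C":   {"C": 9,  "H": 14, "N": 3, "O": 7, "P": 1},
    "G":   {"C": 10, "H": 14, "N": 5, "O": 7, "P": 1},
    "T":   {"C": 10, "H": 15, "N": 2, "O": 8, "P": 1},
    "U":   {"C": 9,  "H": 13, "N": 2, "O": 8, "P": 1},
    "AP":  {"C": 5,  "H": 11, "N": 0, "O": 7, "P": 1},
    "rAP": {"C": 5,  "H": 13, "N": 0, "O": 7, "P": 1},
    "F":   {"C": 5,  "H": 11, "N": 0, "O": 6, "P": 1}
  },
  "heavy_substitution": {
    "A": {"C13": 10, "N15": 5},
    "G": {"C13": 10, "N15": 5}
  }
}
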