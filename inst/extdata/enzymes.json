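{
  "comment": "Restriction/nicking enzyme table. Recognition strings are IUPAC-degenerate, written 5'->3' on the top strand. Cut offsets count from the 5' end of the recognition string on each strand (supplier convention); offsets beyond the recognition length denote cuts outside the site (nicking enzymes). 'nicking' is one of none/top/bottom.",
  "enzymes": [
    {"name": "NdeI",     "recognition": "CATATG",  "cut_offset_top": 2, "cut_offset_bottom": 4, "nicking": "none"},
    {"name": "HaeII",    "recognition": "RGCGCY",  "cut_offset_top": 5, "cut_offset_bottom": 1, "nicking": "none"},
    {"name": "PstI",     "recognition": "CTGCAG",  "cut_offset_top": 5, "cut_offset_bottom": 1, "nicking": "none"},
    {"name": "BsoBI",    "recognition": "CYCGRG",  "cut_offset_top": 1, "cut_offset_bottom": 5, "nicking": "none"},
    {"name": "Nt.BspQI", "recognition": "GCTCTTC", "cut_offset_top": 8, "cut_offset_bottom": null, "nicking": "top"},
    {"name": "Nb.BbvCI", "recognition": "CCTCAGC", "cut_offset_top": null, "cut_offset_bottom": 5, "nicking": "bottom"}
  ]
}
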