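{
  "comment": "Allowed residues per diagnostic position (ar/R filter TMH2, TMH5, LE1, LE2; then P1-P5) for each atypical substrate.",
  "positions": ["TMH2", "TMH5", "LE1", "LE2", "P1", "P2", "P3", "P4", "P5"],
  "rules": {
    "NH3": [["H", "W"], ["I", "V"], ["G", "A"], ["R"],
            ["T", "F"], ["S"], ["A"], ["Y"], ["W", "L"]],
    "boron": [["F", "A", "G"], ["H", "I", "S"], ["T", "G", "A"], ["R"],
              ["Q", "F", "I"], ["S", "T"], ["A"], ["F", "Y"], ["W", "L"]],
    "CO2": [["F"], ["H"], ["T"], ["R"],
            ["Q", "M"], ["S"], ["A"], ["F"], ["W"]],
    "H2O2": [["H", "F", "W"], ["I", "H", "V"], ["A", "T", "G"], ["R", "V"],
             ["T", "Q", "F"], ["S", "A"], ["A"], ["Y", "F"], ["W", "I"]],
    "urea": [["F", "H", "G", "A", "N"], ["I", "H", "S", "V"],
             ["T", "A", "G"], ["R", "V"],
             ["M", "T", "Q", "L", "F", "V", "I"], ["S", "A", "T"], ["A"],
             ["F", "Y"], ["W", "F", "L"]]
  }
}
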