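{
  "id": "example01",
  "units": {"length": "cm", "area": "cm2"},
  "linear": {"ivs": 1.0, "lvid": 4.5, "pwt": 1.0},
  "sax": {"a1": 50.26548245743669, "a2": 28.274333882308138, "level": "chordae"},
  "long_axis": {"a": 4.8, "d": 3.2},
  "disc_stack": {
    "a": [2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2],
    "b": [2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2],
    "length_4ch": 8,
    "length_2ch": 8
  },
  "subject": {"age_years": 45, "sex": "M", "bsa_m2": 2.0}
}
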