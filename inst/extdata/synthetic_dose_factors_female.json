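{
  "_comment": "SYNTHETIC dose-factor fixture for the adult female phantom: plausible magnitudes for 177Lu (slightly larger factors / smaller masses than the male fixture). NOT values from OLINDA/EXM or any published phantom library.",
  "phantom_sex": "female",
  "phantom_mass_g": {
    "kidneys": 260,
    "liver": 1400,
    "spleen": 150,
    "bone_marrow": 900
  },
  "dcf_tumor": 0.0236,
  "df_remainder_to_marrow": 3.58e-05,
  "factors": [
    {"source": "kidneys", "target": "kidneys", "value": 2.9e-04, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "liver", "target": "kidneys", "value": 3.7e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "spleen", "target": "kidneys", "value": 6.3e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "remainder", "target": "kidneys", "value": 1.7e-06, "kind": "concentration", "units": "mGy*kg/(MBq*s)"},
    {"source": "liver", "target": "liver", "value": 5.6e-05, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "kidneys", "target": "liver", "value": 3.7e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "spleen", "target": "liver", "value": 1.7e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "remainder", "target": "liver", "value": 1.4e-06, "kind": "concentration", "units": "mGy*kg/(MBq*s)"},
    {"source": "spleen", "target": "spleen", "value": 4.7e-04, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "kidneys", "target": "spleen", "value": 6.3e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "liver", "target": "spleen", "value": 1.7e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "remainder", "target": "spleen", "value": 1.7e-06, "kind": "concentration", "units": "mGy*kg/(MBq*s)"},
    {"source": "bone_marrow", "target": "bone_marrow", "value": 9.2e-06, "kind": "concentration", "units": "mGy*kg/(MBq*s)"},
    {"source": "kidneys", "target": "bone_marrow", "value": 1.3e-06, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "liver", "target": "bone_marrow", "value": 1.0e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "spleen", "target": "bone_marrow", "value": 1.4e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"}
  ]
}
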