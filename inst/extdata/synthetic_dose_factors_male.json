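{
  "_comment": "SYNTHETIC dose-factor fixture for the adult male phantom: plausible magnitudes for 177Lu chosen so typical DOTA-TATE kinetics yield realistic organ doses. NOT values from OLINDA/EXM or any published phantom library.",
  "phantom_sex": "male",
  "phantom_mass_g": {
    "kidneys": 300,
    "liver": 1800,
    "spleen": 180,
    "bone_marrow": 1100
  },
  "dcf_tumor": 0.0236,
  "df_remainder_to_marrow": 3.03e-05,
  "factors": [
    {"source": "kidneys", "target": "kidneys", "value": 2.5e-04, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "liver", "target": "kidneys", "value": 3.2e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "spleen", "target": "kidneys", "value": 5.5e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "remainder", "target": "kidneys", "value": 1.5e-06, "kind": "concentration", "units": "mGy*kg/(MBq*s)"},
    {"source": "liver", "target": "liver", "value": 4.5e-05, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "kidneys", "target": "liver", "value": 3.2e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "spleen", "target": "liver", "value": 1.5e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "remainder", "target": "liver", "value": 1.2e-06, "kind": "concentration", "units": "mGy*kg/(MBq*s)"},
    {"source": "spleen", "target": "spleen", "value": 4.0e-04, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "kidneys", "target": "spleen", "value": 5.5e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "liver", "target": "spleen", "value": 1.5e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "remainder", "target": "spleen", "value": 1.5e-06, "kind": "concentration", "units": "mGy*kg/(MBq*s)"},
    {"source": "bone_marrow", "target": "bone_marrow", "value": 8.0e-06, "kind": "concentration", "units": "mGy*kg/(MBq*s)"},
    {"source": "kidneys", "target": "bone_marrow", "value": 1.1e-06, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "liver", "target": "bone_marrow", "value": 9.0e-08, "kind": "organ_level", "units": "mGy/(MBq*s)"},
    {"source": "spleen", "target": "bone_marrow", "value": 1.2e-07, "kind": "organ_level", "units": "mGy/(MBq*s)"}
  ]
}
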