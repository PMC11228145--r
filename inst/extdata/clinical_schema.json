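{
  "target_name": "blood_glucose",
  "attributes": [
    {"attribute_id": "A1", "name": "age",          "group_id": "A", "kind": "numeric"},
    {"attribute_id": "A2", "name": "gender",       "group_id": "A", "kind": "categorical"},
    {"attribute_id": "B1", "name": "AST",          "group_id": "B", "kind": "numeric"},
    {"attribute_id": "B2", "name": "ALT",          "group_id": "B", "kind": "numeric"},
    {"attribute_id": "B3", "name": "ALP",          "group_id": "B", "kind": "numeric"},
    {"attribute_id": "B4", "name": "GGT",          "group_id": "B", "kind": "numeric"},
    {"attribute_id": "B5", "name": "total_protein","group_id": "B", "kind": "numeric"},
    {"attribute_id": "B6", "name": "albumin",      "group_id": "B", "kind": "numeric"},
    {"attribute_id": "B7", "name": "globulin",     "group_id": "B", "kind": "numeric"},
    {"attribute_id": "B8", "name": "AG_ratio",     "group_id": "B", "kind": "numeric"},
    {"attribute_id": "C1", "name": "urea",         "group_id": "C", "kind": "numeric"},
    {"attribute_id": "C2", "name": "creatinine",   "group_id": "C", "kind": "numeric"},
    {"attribute_id": "C3", "name": "uric_acid",    "group_id": "C", "kind": "numeric"},
    {"attribute_id": "D1", "name": "TG",           "group_id": "D", "kind": "numeric"},
    {"attribute_id": "D2", "name": "TC",           "group_id": "D", "kind": "numeric"},
    {"attribute_id": "D3", "name": "HDL_C",        "group_id": "D", "kind": "numeric"},
    {"attribute_id": "D4", "name": "LDL_C",        "group_id": "D", "kind": "numeric"},
    {"attribute_id": "E1", "name": "HBsAg",        "group_id": "E", "kind": "numeric"},
    {"attribute_id": "E2", "name": "HBsAb",        "group_id": "E", "kind": "numeric"},
    {"attribute_id": "E3", "name": "HBeAg",        "group_id": "E", "kind": "numeric"},
    {"attribute_id": "E4", "name": "HBeAb",        "group_id": "E", "kind": "numeric"},
    {"attribute_id": "E5", "name": "HBcAb",        "group_id": "E", "kind": "numeric"},
    {"attribute_id": "F1", "name": "WBC",          "group_id": "F", "kind": "numeric"},
    {"attribute_id": "F2", "name": "RBC",          "group_id": "F", "kind": "numeric"},
    {"attribute_id": "F3", "name": "HGB",          "group_id": "F", "kind": "numeric"},
    {"attribute_id": "F4", "name": "HCT",          "group_id": "F", "kind": "numeric"},
    {"attribute_id": "F5", "name": "MCV",          "group_id": "F", "kind": "numeric"},
    {"attribute_id": "F6", "name": "MCH",          "group_id": "F", "kind": "numeric"},
    {"attribute_id": "F7", "name": "MCHC",         "group_id": "F", "kind": "numeric"},
    {"attribute_id": "F8", "name": "RDW",          "group_id": "F", "kind": "numeric"},
    {"attribute_id": "F9", "name": "platelets",    "group_id": "F", "kind": "numeric"},
    {"attribute_id": "F10","name": "MPV",          "group_id": "F", "kind": "numeric"},
    {"attribute_id": "F11","name": "PDW",          "group_id": "F", "kind": "numeric"},
    {"attribute_id": "F12","name": "PCT",          "group_id": "F", "kind": "numeric"},
    {"attribute_id": "G1", "name": "neut_pct",     "group_id": "G", "kind": "numeric"},
    {"attribute_id": "G2", "name": "lymph_pct",    "group_id": "G", "kind": "numeric"},
    {"attribute_id": "G3", "name": "mono_pct",     "group_id": "G", "kind": "numeric"},
    {"attribute_id": "G4", "name": "eos_pct",      "group_id": "G", "kind": "numeric"},
    {"attribute_id": "G5", "name": "baso_pct",     "group_id": "G", "kind": "numeric"}
  ]
}
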