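{
  "description": "Comparison of indirect and tractography-based targets for 18 consecutive essential-tremor MRgHIFU cases, transcribed from the published case table. Coordinates are AC-PC frame mm: L lateral (treated side positive), A anterior of PC, S superior of the AC-PC plane. The indirect target is tabulated at S = 0 but the printed Euclidean-distance column assumes it sits 2 mm above the AC-PC plane. printed_offset_mm is the distance column exactly as printed.",
  "convention": {"indirect_s_mm": 2, "offset_rounding_decimals": 2},
  "cases": [
    {"case": 1,  "side": "L", "indirect": {"L": 14,   "A": 7.1, "S": 0}, "target1": {"L": 13.8, "A": 8.1, "S": 2},   "target2": {"L": 14.6, "A": 8.1, "S": 3.3}, "printed_offset_mm": 1.02},
    {"case": 2,  "side": "L", "indirect": {"L": 14,   "A": 7.4, "S": 0}, "target1": {"L": 13.2, "A": 7.5, "S": 2},   "target2": {"L": 13.2, "A": 7.5, "S": 4},   "printed_offset_mm": 0.81},
    {"case": 3,  "side": "L", "indirect": {"L": 14,   "A": 6.4, "S": 0}, "target1": {"L": 13.8, "A": 8.3, "S": 3.5}, "target2": {"L": 15,   "A": 8.3, "S": 5},   "printed_offset_mm": 2.43},
    {"case": 4,  "side": "L", "indirect": {"L": 14,   "A": 6.5, "S": 0}, "target1": {"L": 13,   "A": 5.5, "S": 2},   "target2": {"L": 14.5, "A": 6.3, "S": 5},   "printed_offset_mm": 1.41},
    {"case": 5,  "side": "L", "indirect": {"L": 14,   "A": 7.5, "S": 0}, "target1": {"L": 13.9, "A": 8,   "S": 2},   "target2": {"L": 16.2, "A": 8.4, "S": 4},   "printed_offset_mm": 0.51},
    {"case": 6,  "side": "L", "indirect": {"L": 14,   "A": 6.9, "S": 0}, "target1": {"L": 11.7, "A": 6.4, "S": 2},   "target2": {"L": 15.1, "A": 5.3, "S": 4},   "printed_offset_mm": 2.35,
     "notes": "second-target A printed as 'P5.3 mm' (ambiguous P prefix); stored as 5.3, consistent with the printed second-target A mean"},
    {"case": 7,  "side": "L", "indirect": {"L": 14,   "A": 6.4, "S": 0}, "target1": {"L": 12.5, "A": 6.5, "S": 2},   "target2": {"L": 12.5, "A": 4.5, "S": 4},   "printed_offset_mm": 1.50},
    {"case": 8,  "side": "L", "indirect": {"L": 14,   "A": 7.4, "S": 0}, "target1": {"L": 13.3, "A": 7.6, "S": 0.2}, "target2": {"L": 17.7, "A": 9,   "S": 2},   "printed_offset_mm": 1.94},
    {"case": 9,  "side": "L", "indirect": {"L": 14,   "A": 7,   "S": 0}, "target1": {"L": 14.5, "A": 8,   "S": 2},   "target2": {"L": 16,   "A": 8,   "S": 4},   "printed_offset_mm": 1.12},
    {"case": 10, "side": "L", "indirect": {"L": 14,   "A": 7.6, "S": 0}, "target1": {"L": 13,   "A": 8.3, "S": 2.5}, "target2": {"L": 15.1, "A": 8.5, "S": 4.1}, "printed_offset_mm": 1.32},
    {"case": 11, "side": "L", "indirect": {"L": 14,   "A": 6.5, "S": 0}, "target1": {"L": 11.9, "A": 7.1, "S": 2},   "target2": {"L": 12.8, "A": 6.7, "S": 2.9}, "printed_offset_mm": 2.18},
    {"case": 12, "side": "L", "indirect": {"L": 14,   "A": 6.2, "S": 0}, "target1": {"L": 9.7,  "A": 6.9, "S": 1.4}, "target2": null,                            "printed_offset_mm": 4.40,
     "notes": "no second target"},
    {"case": 13, "side": "L", "indirect": {"L": 14,   "A": 7,   "S": 0}, "target1": {"L": 13,   "A": 8,   "S": 2},   "target2": {"L": 14,   "A": 8.5, "S": 4},   "printed_offset_mm": 1.41},
    {"case": 14, "side": "R", "indirect": {"L": 14,   "A": 6.7, "S": 0}, "target1": {"L": 12,   "A": 7.9, "S": 2},   "target2": {"L": 12,   "A": 8.5, "S": 4},   "printed_offset_mm": 2.33,
     "notes": "targets printed with R (right) prefix; stored as treated-side-positive lateral coordinates"},
    {"case": 15, "side": "L", "indirect": {"L": 14,   "A": 7,   "S": 0}, "target1": {"L": 12.4, "A": 7.9, "S": 1.5}, "target2": {"L": 13.3, "A": 8,   "S": 2.5}, "printed_offset_mm": 1.90},
    {"case": 16, "side": "L", "indirect": {"L": 14.5, "A": 6.5, "S": 0}, "target1": {"L": 14.4, "A": 7.5, "S": 2},   "target2": {"L": 15,   "A": 8,   "S": 4.1}, "printed_offset_mm": 2.23,
     "notes": "printed distance does not reproduce from the printed coordinates under the stated indirect-S=2 convention (computed 1.00); it matches an indirect-S=0 computation truncated to 2 decimals (2.238)"},
    {"case": 17, "side": "L", "indirect": {"L": 14,   "A": 5.8, "S": 0}, "target1": {"L": 14,   "A": 5.8, "S": 2},   "target2": {"L": 15,   "A": 5.8, "S": 4},   "printed_offset_mm": 1.00,
     "notes": "printed distance does not reproduce from the printed coordinates under either S convention (coordinates are identical to the indirect target apart from S: computed 0.00 at S=2, 2.00 at S=0)"},
    {"case": 18, "side": "L", "indirect": {"L": 14.2, "A": 7,   "S": 0}, "target1": {"L": 13.8, "A": 7,   "S": 2},   "target2": {"L": 13.8, "A": 7.5, "S": 4.4}, "printed_offset_mm": 2.03,
     "notes": "printed distance does not reproduce under the stated indirect-S=2 convention (computed 0.40); it matches an indirect-S=0 computation truncated to 2 decimals (2.0396)"}
  ],
  "printed_average_row": {
    "indirect":  {"L_mean": 14.03, "L_sd": 0.12, "A_mean": 6.8, "A_sd": 0.49, "S_mean": 0},
    "target1":   {"L_mean": 13.0,  "L_sd": 1.17, "A_mean": 7.4, "A_sd": 0.85, "S_mean": 2.0, "S_sd": 0.61},
    "target2":   {"L_mean": 14.5,  "L_sd": 1.45, "A_mean": 7.5, "A_sd": 1.16, "S_mean": 3.8, "S_sd": 0.78},
    "offset_mm": {"mean": 1.8, "sd": 0.88,
                  "note": "the printed cohort mean 1.80 differs from the mean of the printed per-case column (1.77 before rounding); likely computed from unrounded coordinates"}
  }
}
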