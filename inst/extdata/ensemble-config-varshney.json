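{
  "comment": "Full-study ensemble configuration for the hermaphrodite somatic connectome. Supply the wiring tables (not bundled) as CSV in the dialects documented in ?loadConnectome, then run: Rscript inst/scripts/fas-pipeline.R ensemble --config <this file> --out <dir>. The run is long (hours on one CPU).",
  "connectome": {
    "gap": "varshney_gap.csv",
    "syn": "varshney_syn.csv",
    "polarity": "varshney_polarity.csv",
    "filterSomatic": true,
    "pharyngeal": ["I1L", "I1R", "I2L", "I2R", "I3", "I4", "I5", "I6",
                   "M1", "M2L", "M2R", "M3L", "M3R", "M4", "M5",
                   "MCL", "MCR", "MI", "NSML", "NSMR"],
    "expectedNeurons": 279
  },
  "groups": {
    "input": ["PLML", "PLMR"],
    "forward_motor_classes": ["DB", "VB", "DD", "VD"]
  },
  "histogram": "swelling_histogram.csv",
  "params": {
    "C_pF": 1, "Gc_pS": 10, "Ecell_mV": -35, "g_pS": 100,
    "Eexc_mV": 0, "Einh_mV": -45, "beta_per_mV": 0.125,
    "ar_per_s": 1, "ad_per_s": 5, "dt_s": 1e-4
  },
  "inputCurrent": 2e4,
  "K": 1447,
  "seed": 1,
  "Thealthy": 25,
  "Tinit": 20,
  "transient": 5,
  "N": 200,
  "minLeaf": 40,
  "leafSizeSweep": [5, 10, 20, 40, 80, 160],
  "baselineTrials": 100,
  "featureGrid": 20
}
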