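{
  "context": {
    "threshold": 20000,
    "occupancy_rate": 1,
    "excess_demand": true,
    "objective": "nmb",
    "perspective": "provider",
    "currency": "£"
  },
  "chosen": "P1",
  "options": [
    {"id": "P1", "los_per_patient": 10, "expenditure_per_patient": 7000, "variable_cost_per_patient": 3500, "revenue_per_patient": 9000, "qaly_gain_per_patient": 1.3},
    {"id": "P2", "los_per_patient": 5, "expenditure_per_patient": 5000, "variable_cost_per_patient": null, "revenue_per_patient": 6000, "qaly_gain_per_patient": 0.6},
    {"id": "P3", "los_per_patient": 5, "expenditure_per_patient": 5000, "variable_cost_per_patient": null, "revenue_per_patient": 5500, "qaly_gain_per_patient": 0.4}
  ]
}
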