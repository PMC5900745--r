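# threshold: 20000
# occupancy_rate: 1
# excess_demand: true
# objective: nmb
# perspective: provider
# currency: £
# chosen: P1
id,los_per_patient,expenditure_per_patient,variable_cost_per_patient,revenue_per_patient,qaly_gain_per_patient
P1,10,7000,3500,9000,1.3
P2,5,5000,,6000,0.6
P3,5,5000,,5500,0.4
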