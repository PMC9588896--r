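{
  "comment": "Synthetic, illustrative PK/binding parameter set for the bispecific anti-VEGF/Ang-2 nanobody simulator. NOT estimates from any study: the published model's fitted values are unavailable. Chosen so that 360 to 720 mg every-3-weeks spans the transition from partial to near-complete population-level trough target engagement of Ang-2, while VEGF-A is suppressed >90% at all study doses.",
  "pk": {
    "clearance": 0.45,
    "central_volume": 3.0,
    "intercompartmental_clearance": 0.5,
    "peripheral_volume": 2.5
  },
  "ligands": [
    {"name": "Ang-2", "k_on": 1.0, "k_off": 1.0, "k_syn": 5.0, "k_deg": 5.0, "k_int": 0.5},
    {"name": "VEGF-A", "k_on": 5.0, "k_off": 0.2, "k_syn": 2.0, "k_deg": 2.0, "k_int": 1.0}
  ],
  "regimen": {
    "dose_mg": 720,
    "molecular_weight": 40000,
    "infusion_duration_hr": 1,
    "interval_days": 21,
    "n_doses": 1
  },
  "omega": {
    "clearance": 0.3,
    "central_volume": 0.2,
    "k_syn": 0.3,
    "k_deg": 0.3
  }
}
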