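{
  "beta": 0.8,
  "delta": 0.9,
  "u_healthy": 1,
  "u_sick": 0,
  "p_adherent": 0.9,
  "p_nonadherent": 0.6,
  "cost_model": {"uniform": {"c_max": 0.5}},
  "bonus": 0,
  "detection_prob": 1,
  "admin_share": 0,
  "cost_adherent": 0.05,
  "cost_nonadherent": 0.01,
  "followup_cost": 1
}
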