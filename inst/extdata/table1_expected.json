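{
  "comment": "Published per-group electrostatic stabilization values (kcal/mol) for the worked-example snapshot table; used as the CLI efield check file.",
  "catalyzed": {
    "bulk_water": 9.02,
    "complexed_water": -13.62,
    "cage": -1.04
  },
  "uncatalyzed": {
    "bulk_water": 10.58,
    "complexed_water": -11.29
  },
  "net_contribution_magnitude": 4.9
}
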