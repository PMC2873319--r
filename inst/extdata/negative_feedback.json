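{
  "schema": "synmotif-model/1",
  "species": [
    {
      "name": "B",
      "initial": 1,
      "pool_partner": "B_P",
      "pool_total": 1
    },
    {
      "name": "B_P",
      "initial": 0
    },
    {
      "name": "C",
      "initial": 1,
      "pool_partner": "C_P",
      "pool_total": 1
    },
    {
      "name": "C_P",
      "initial": 0
    }
  ],
  "reactions": [
    {
      "label": "activation_B",
      "kind": "mm_activation",
      "substrate": "B",
      "product": "B_P",
      "modifier": "A",
      "vmax": 1,
      "km": 0.5
    },
    {
      "label": "deactivation_B",
      "kind": "mm_deactivation",
      "substrate": "B_P",
      "product": "B",
      "vmax": 0.5,
      "km": 0.5
    },
    {
      "label": "activation_C",
      "kind": "mm_activation",
      "substrate": "C",
      "product": "C_P",
      "modifier": "B_P",
      "vmax": 1,
      "km": 0.5
    },
    {
      "label": "deactivation_C",
      "kind": "mm_deactivation",
      "substrate": "C_P",
      "product": "C",
      "vmax": 0.5,
      "km": 0.5
    },
    {
      "label": "feedback_B",
      "kind": "mm_deactivation",
      "substrate": "B_P",
      "product": "B",
      "modifier": "C_P",
      "vmax": 1,
      "km": 0.5
    }
  ],
  "output": "C_P",
  "inputs": {
    "A": 1
  }
}
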