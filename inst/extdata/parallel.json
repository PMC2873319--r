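{
  "schema": "synmotif-model/1",
  "species": [
    {
      "name": "B1",
      "initial": 1,
      "pool_partner": "B1_P",
      "pool_total": 1
    },
    {
      "name": "B1_P",
      "initial": 0
    },
    {
      "name": "B2",
      "initial": 1,
      "pool_partner": "B2_P",
      "pool_total": 1
    },
    {
      "name": "B2_P",
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
      "label": "activation_B1",
      "kind": "mm_activation",
      "substrate": "B1",
      "product": "B1_P",
      "modifier": "A1",
      "vmax": 1,
      "km": 0.5
    },
    {
      "label": "deactivation_B1",
      "kind": "mm_deactivation",
      "substrate": "B1_P",
      "product": "B1",
      "vmax": 0.5,
      "km": 0.5
    },
    {
      "label": "activation_B2",
      "kind": "mm_activation",
      "substrate": "B2",
      "product": "B2_P",
      "modifier": "A2",
      "vmax": 1,
      "km": 0.5
    },
    {
      "label": "deactivation_B2",
      "kind": "mm_deactivation",
      "substrate": "B2_P",
      "product": "B2",
      "vmax": 0.5,
      "km": 0.5
    },
    {
      "label": "activation_C_via_B1",
      "kind": "mm_activation",
      "substrate": "C",
      "product": "C_P",
      "modifier": "B1_P",
      "vmax": 1,
      "km": 0.5
    },
    {
      "label": "activation_C_via_B2",
      "kind": "mm_activation",
      "substrate": "C",
      "product": "C_P",
      "modifier": "B2_P",
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
    }
  ],
  "output": "C_P",
  "inputs": {
    "A1": 1,
    "A2": 1
  }
}
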