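{
  "schema": "synmotif-model/1",
  "species": [
    {
      "name": "IKKK",
      "initial": 1,
      "pool_partner": "IKKK_P",
      "pool_total": 1
    },
    {
      "name": "IKKK_P",
      "initial": 0
    },
    {
      "name": "IKK",
      "initial": 1,
      "pool_partner": "IKK_P",
      "pool_total": 1
    },
    {
      "name": "IKK_P",
      "initial": 0
    },
    {
      "name": "NFkB_IkB",
      "initial": 1
    },
    {
      "name": "NFkB_IkB_p",
      "initial": 0
    },
    {
      "name": "NFkB",
      "initial": 0
    },
    {
      "name": "IkB",
      "initial": 0.5
    },
    {
      "name": "ICAM1",
      "initial": 0
    }
  ],
  "reactions": [
    {
      "label": "activation_IKKK",
      "kind": "mm_activation",
      "substrate": "IKKK",
      "product": "IKKK_P",
      "modifier": "TNF",
      "vmax": 1,
      "km": 0.5
    },
    {
      "label": "deactivation_IKKK",
      "kind": "mm_deactivation",
      "substrate": "IKKK_P",
      "product": "IKKK",
      "vmax": 0.5,
      "km": 0.5
    },
    {
      "label": "activation_IKK",
      "kind": "mm_activation",
      "substrate": "IKK",
      "product": "IKK_P",
      "modifier": "IKKK_P",
      "vmax": 1,
      "km": 0.5
    },
    {
      "label": "deactivation_IKK",
      "kind": "mm_deactivation",
      "substrate": "IKK_P",
      "product": "IKK",
      "vmax": 0.5,
      "km": 0.5
    },
    {
      "label": "phosphorylation_IkB",
      "kind": "mass_action",
      "substrate": "NFkB_IkB",
      "product": "NFkB_IkB_p",
      "modifier": "IKK_P",
      "k": 2
    },
    {
      "label": "degradation_IkB",
      "kind": "mass_action",
      "substrate": "NFkB_IkB_p",
      "product": "NFkB",
      "k": 2
    },
    {
      "label": "sequestration_NFkB",
      "kind": "mass_action",
      "substrate": "NFkB",
      "product": "NFkB_IkB",
      "modifier": "IkB",
      "k": 4
    },
    {
      "label": "synthesis_IkB",
      "kind": "zeroth_synthesis",
      "product": "IkB",
      "modifier": "NFkB",
      "k": 0.4
    },
    {
      "label": "turnover_IkB",
      "kind": "first_degradation",
      "substrate": "IkB",
      "k": 0.2
    },
    {
      "label": "expression_ICAM1",
      "kind": "zeroth_synthesis",
      "product": "ICAM1",
      "modifier": "NFkB",
      "k": 1
    },
    {
      "label": "turnover_ICAM1",
      "kind": "first_degradation",
      "substrate": "ICAM1",
      "k": 0.5
    }
  ],
  "output": "ICAM1",
  "inputs": {
    "TNF": 1
  }
}
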