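{
  "female": {
    "level": "full",
    "micro_target": "rda",
    "macro_energy_bounds": [
      {
        "nutrient_id": "protein",
        "lower": 10,
        "upper": 35
      },
      {
        "nutrient_id": "carbohydrate",
        "lower": 45,
        "upper": 65
      },
      {
        "nutrient_id": "fat",
        "lower": 20,
        "upper": 35
      },
      {
        "nutrient_id": "sfa",
        "lower": null,
        "upper": 10
      }
    ],
    "macro_mass_bounds": [
      {
        "nutrient_id": "fiber",
        "lower": 28,
        "upper": null
      },
      {
        "nutrient_id": "sodium",
        "lower": null,
        "upper": 2300
      }
    ],
    "micro_refs": [
      {
        "nutrient_id": "calcium",
        "rda": 1000,
        "ear": 800
      },
      {
        "nutrient_id": "folate",
        "rda": 400,
        "ear": 320
      },
      {
        "nutrient_id": "iron",
        "rda": 18,
        "ear": 8.1
      },
      {
        "nutrient_id": "magnesium",
        "rda": 310,
        "ear": 255
      },
      {
        "nutrient_id": "vit_a",
        "rda": 700,
        "ear": 500
      },
      {
        "nutrient_id": "vit_e",
        "rda": 15,
        "ear": 12
      }
    ]
  },
  "male": {
    "level": "full",
    "micro_target": "rda",
    "macro_energy_bounds": [
      {
        "nutrient_id": "protein",
        "lower": 10,
        "upper": 35
      },
      {
        "nutrient_id": "carbohydrate",
        "lower": 45,
        "upper": 65
      },
      {
        "nutrient_id": "fat",
        "lower": 20,
        "upper": 35
      },
      {
        "nutrient_id": "sfa",
        "lower": null,
        "upper": 10
      }
    ],
    "macro_mass_bounds": [
      {
        "nutrient_id": "fiber",
        "lower": 36.4,
        "upper": null
      },
      {
        "nutrient_id": "sodium",
        "lower": null,
        "upper": 2300
      }
    ],
    "micro_refs": [
      {
        "nutrient_id": "calcium",
        "rda": 1000,
        "ear": 800
      },
      {
        "nutrient_id": "folate",
        "rda": 400,
        "ear": 320
      },
      {
        "nutrient_id": "iron",
        "rda": 8,
        "ear": 6
      },
      {
        "nutrient_id": "magnesium",
        "rda": 400,
        "ear": 330
      },
      {
        "nutrient_id": "vit_a",
        "rda": 900,
        "ear": 625
      },
      {
        "nutrient_id": "vit_e",
        "rda": 15,
        "ear": 12
      }
    ]
  }
}
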