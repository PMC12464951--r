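{
  "population": {
    "n_flowers": 100,
    "range_lo": 0,
    "range_hi": 1,
    "pollen_budget": 160000
  },
  "guild": [
    {
      "label": "bee",
      "attraction": {
        "form": "gaussian",
        "optimum": 0.25,
        "peak_value": 0.9,
        "reference_point": 0.75,
        "reference_value": 0.1,
        "label": "bee attraction"
      },
      "removal": {
        "form": "gaussian",
        "optimum": 0.25,
        "peak_value": 10000,
        "reference_point": 0.75,
        "reference_value": 2500,
        "label": "bee removal"
      },
      "transfer_efficiency": 0.02
    },
    {
      "label": "hummingbird",
      "attraction": {
        "form": "gaussian",
        "optimum": 0.75,
        "peak_value": 0.9,
        "reference_point": 0.25,
        "reference_value": 0.1,
        "label": "hummingbird attraction"
      },
      "removal": {
        "form": "gaussian",
        "optimum": 0.75,
        "peak_value": 10000,
        "reference_point": 0.25,
        "reference_value": 2500,
        "label": "hummingbird removal"
      },
      "transfer_efficiency": 0.04
    }
  ],
  "environment": {
    "mixture": [0.5, 0.5],
    "total_visits": 3500,
    "n_iterations": 10,
    "seed": 1
  },
  "analysis": {
    "n_bins": 20,
    "bandwidth": 0.15
  }
}
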