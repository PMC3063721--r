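{
  "name": "density8",
  "n_neurons": 9,
  "baseline_rate_hz": 18,
  "delta_s": 0.001,
  "refractory_s": 0.001,
  "refractory_neurons": [
    1,
    2,
    3,
    4,
    5,
    6,
    7,
    8
  ],
  "hidden_neurons": [],
  "noise_snr_db": null,
  "edges": [
    {
      "trigger": 1,
      "target": 1,
      "lags": [
        -0.6,
        -0.5,
        -0.4
      ]
    },
    {
      "trigger": 2,
      "target": 2,
      "lags": [
        -0.6,
        -0.5,
        -0.4
      ]
    },
    {
      "trigger": 3,
      "target": 3,
      "lags": [
        -0.6,
        -0.5,
        -0.4
      ]
    },
    {
      "trigger": 4,
      "target": 4,
      "lags": [
        -0.6,
        -0.5,
        -0.4
      ]
    },
    {
      "trigger": 5,
      "target": 5,
      "lags": [
        -0.6,
        -0.5,
        -0.4
      ]
    },
    {
      "trigger": 6,
      "target": 6,
      "lags": [
        -0.6,
        -0.5,
        -0.4
      ]
    },
    {
      "trigger": 7,
      "target": 7,
      "lags": [
        -0.6,
        -0.5,
        -0.4
      ]
    },
    {
      "trigger": 8,
      "target": 8,
      "lags": [
        -0.6,
        -0.5,
        -0.4
      ]
    }
  ]
}
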