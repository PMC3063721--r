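{
  "name": "hidden5",
  "n_neurons": 5,
  "baseline_rate_hz": 18,
  "delta_s": 0.001,
  "refractory_s": 0.001,
  "refractory_neurons": [
    1,
    2,
    3,
    4,
    5
  ],
  "hidden_neurons": [
    4,
    5
  ],
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
      "trigger": 1,
      "target": 2,
      "lags": [
        1,
        2,
        2
      ]
    },
    {
      "trigger": 2,
      "target": 3,
      "lags": [
        1,
        2,
        2
      ]
    },
    {
      "trigger": 3,
      "target": 1,
      "lags": [
        1,
        2,
        2
      ]
    },
    {
      "trigger": 2,
      "target": 1,
      "lags": [
        -0.8,
        -0.6,
        -0.3
      ]
    },
    {
      "trigger": 3,
      "target": 2,
      "lags": [
        -0.8,
        -0.6,
        -0.3
      ]
    },
    {
      "trigger": 1,
      "target": 3,
      "lags": [
        -0.8,
        -0.6,
        -0.3
      ]
    },
    {
      "trigger": 1,
      "target": 4,
      "lags": [
        0,
        0,
        1,
        2,
        2,
        1
      ]
    },
    {
      "trigger": 4,
      "target": 1,
      "lags": [
        0,
        0,
        1,
        2,
        2,
        1
      ]
    },
    {
      "trigger": 1,
      "target": 5,
      "lags": [
        0,
        0,
        1,
        2,
        2,
        1
      ]
    },
    {
      "trigger": 5,
      "target": 1,
      "lags": [
        0,
        0,
        1,
        2,
        2,
        1
      ]
    }
  ]
}
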