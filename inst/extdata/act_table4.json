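{
  "name": "act_table4",
  "max_duration_s": 480,
  "conditions": [
    {
      "condition": 1,
      "varied": "reward_frequency",
      "components": [
        {
          "component": 1,
          "reward": {
            "prob": [0.25, 0.75],
            "mean": [50, 50],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [30, 30],
            "variable": [false, false]
          },
          "net": [100, 600]
        },
        {
          "component": 2,
          "reward": {
            "prob": [0.35, 0.65],
            "mean": [50, 50],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [30, 30],
            "variable": [false, false]
          },
          "net": [200, 500]
        },
        {
          "component": 3,
          "reward": {
            "prob": [0.65, 0.35],
            "mean": [50, 50],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [30, 30],
            "variable": [false, false]
          },
          "net": [500, 200]
        },
        {
          "component": 4,
          "reward": {
            "prob": [0.75, 0.25],
            "mean": [50, 50],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [30, 30],
            "variable": [false, false]
          },
          "net": [600, 100]
        }
      ]
    },
    {
      "condition": 2,
      "varied": "reward_magnitude",
      "components": [
        {
          "component": 1,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [25, 75],
            "variable": [true, true]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [30, 30],
            "variable": [false, false]
          },
          "net": [100, 600]
        },
        {
          "component": 2,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [35, 65],
            "variable": [true, true]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [30, 30],
            "variable": [false, false]
          },
          "net": [200, 500]
        },
        {
          "component": 3,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [65, 35],
            "variable": [true, true]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [30, 30],
            "variable": [false, false]
          },
          "net": [500, 200]
        },
        {
          "component": 4,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [75, 25],
            "variable": [true, true]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [30, 30],
            "variable": [false, false]
          },
          "net": [600, 100]
        }
      ]
    },
    {
      "condition": 3,
      "varied": "penalty_frequency",
      "components": [
        {
          "component": 1,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [170, 170],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.75, 0.25],
            "mean": [50, 50],
            "variable": [false, false]
          },
          "net": [100, 600]
        },
        {
          "component": 2,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [170, 170],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.65, 0.35],
            "mean": [50, 50],
            "variable": [false, false]
          },
          "net": [200, 500]
        },
        {
          "component": 3,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [170, 170],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.35, 0.65],
            "mean": [50, 50],
            "variable": [false, false]
          },
          "net": [500, 200]
        },
        {
          "component": 4,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [170, 170],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.25, 0.75],
            "mean": [50, 50],
            "variable": [false, false]
          },
          "net": [600, 100]
        }
      ]
    },
    {
      "condition": 4,
      "varied": "penalty_magnitude",
      "components": [
        {
          "component": 1,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [170, 170],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [75, 25],
            "variable": [true, true]
          },
          "net": [100, 600]
        },
        {
          "component": 2,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [170, 170],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [65, 35],
            "variable": [true, true]
          },
          "net": [200, 500]
        },
        {
          "component": 3,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [170, 170],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [35, 65],
            "variable": [true, true]
          },
          "net": [500, 200]
        },
        {
          "component": 4,
          "reward": {
            "prob": [0.5, 0.5],
            "mean": [170, 170],
            "variable": [false, false]
          },
          "penalty": {
            "prob": [0.5, 0.5],
            "mean": [25, 75],
            "variable": [true, true]
          },
          "net": [600, 100]
        }
      ]
    }
  ]
}
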