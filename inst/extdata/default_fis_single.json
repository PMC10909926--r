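{
  "input_names": "force_ratio",
  "directions": "increasing",
  "input_universe": [0, 1.4],
  "input_mfs": {
    "low": {
      "type": "trapezoid",
      "knots": [-0.4, -0.1, 0.1, 0.4]
    },
    "medium": {
      "type": "trapezoid",
      "knots": [0.1, 0.4, 0.6, 0.9]
    },
    "high": {
      "type": "trapezoid",
      "knots": [0.6, 0.9, 1.1, 1.4]
    }
  },
  "output_mfs": {
    "low": {
      "type": "triangle",
      "knots": [0, 0, 1]
    },
    "medium": {
      "type": "triangle",
      "knots": [0, 1, 2]
    },
    "high": {
      "type": "triangle",
      "knots": [1, 2, 2]
    }
  },
  "output_universe": [0, 2],
  "rules": [
    {
      "in1": "low",
      "output": "low"
    },
    {
      "in1": "medium",
      "output": "medium"
    },
    {
      "in1": "high",
      "output": "high"
    }
  ]
}
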