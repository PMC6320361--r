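{
  "description": "Kinetic constants of the six-gene Arabidopsis flowering network (polynomial fit to expression data, Valentim et al. model), with admissible ranges for random draws.",
  "units": {
    "beta": "nM/min",
    "K": "nM",
    "d": "1/min",
    "delta": "days",
    "n": "dimensionless"
  },
  "values": {
    "beta1": 99.8,
    "beta2": 5,
    "beta3": 10,
    "beta4": 22,
    "beta5": 2.4,
    "beta6": 0.79,
    "beta7": 64,
    "beta8": 0.52,
    "beta9": 189,
    "beta10": 8.5,
    "beta11": 100,
    "beta12": 51,
    "K1": 9.82,
    "K2": 700,
    "K3": 10.1,
    "K4": 346,
    "K5": 842,
    "K6": 1011,
    "K7": 695,
    "K8": 1182,
    "K9": 2.4,
    "K10": 4.8,
    "K11": 909,
    "K12": 501,
    "K13": 7.9,
    "K14": 125,
    "K15": 0.63,
    "K16": 985,
    "d1": 0.86,
    "d2": 0.017,
    "d3": 0.11,
    "d4": 0.0075,
    "d5": 0.001,
    "d6": 0.1,
    "delta_days": 0.5,
    "n": 3
  },
  "ranges": {
    "beta": [0.001, 200],
    "K": [0.001, 2000],
    "d": [0.001, 1],
    "delta_days": [0, 1]
  }
}
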