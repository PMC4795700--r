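{
  "k1": 10,
  "k2": 20,
  "k3": 5,
  "k4": 1,
  "k5": 10,
  "k6": 20,
  "k7": 20,
  "k8": 1,
  "gdp": 50,
  "gtp": 500,
  "e0": 0.1,
  "g0": 10,
  "gtpase.mode": "intrinsic",
  "gtpase.kase": 0.1
}
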