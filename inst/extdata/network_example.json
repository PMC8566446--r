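{
  "RandomSeed": {"masterseed": 1234, "place": 11, "detect": 12, "prune": 13, "input": 14},
  "Volume": {
    "Cube": {"type": "cube", "dMin": 1.5e-05, "side": 2e-04, "centre": [0, 0, 0]}
  },
  "PopulationUnits": [
    {"unitID": 1, "volume": "Cube", "neuronTypes": ["bas"], "fraction": 0.2},
    {"unitID": 2, "volume": "Cube", "neuronTypes": ["bas"], "fraction": 0.3}
  ],
  "Connectivity": {
    "bas,bas": {
      "conductance": [2.4e-10, 1e-10],
      "channelParameters": {"tau1": 0.0013, "tau2": 0.012, "failRate": 0.7},
      "modFile": "tmGabaA",
      "pruning": {"f1": 0.5, "softMax": 3, "mu2": 3, "a3": 1.0},
      "pruningOther": {"f1": 0.25, "a3": 0.5}
    }
  },
  "Neurons": {
    "bas": {
      "morphology": "$DATA/ball_and_stick.swc",
      "num": 20, "volumeID": "Cube", "rotationMode": "random",
      "neuronType": "neuron", "type": "bas"
    }
  }
}
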