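{
  "bas": {
    "Ctx": {
      "generator": "poisson",
      "start": [2, 5], "end": [3, 7], "frequency": [4, 2],
      "populationCorrelation": 0.25,
      "nInputs": 20,
      "type": "AMPA_NMDA",
      "conductance": [5e-10, 0],
      "modFile": "tmGlut"
    }
  }
}
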