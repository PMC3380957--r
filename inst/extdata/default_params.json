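{
  "n_sites": 10,
  "p_release": 0.5,
  "tau_rec": 0.5,
  "tau_syn": 0.002,
  "rate": 20,
  "correlation": 0.1,
  "signal": {
    "bandwidth": 0.1,
    "central_frequency": 5,
    "peak_power": 20
  }
}
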