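{
  "narrow": {
    "distribution": "truncnorm",
    "mean": 5.0,
    "sd": 0.1,
    "comment": "tight synchrony: near-step cumulative curves, doses shift entry time"
  },
  "broad": {
    "distribution": "truncnorm",
    "mean": 5.0,
    "sd": 1.0,
    "comment": "HeLa-like: dose-dependent delay with broadened entry times"
  },
  "broad_low": {
    "distribution": "truncnorm",
    "mean": 3.4,
    "sd": 1.0,
    "comment": "U2-OS/RPE1-like: lowered mean, majority censored at full inhibition"
  }
}
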