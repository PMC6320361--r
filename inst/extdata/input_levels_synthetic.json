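{
  "description": "SYNTHETIC constant input levels (nM) for SVP_m (x7), FLC_m (x8), SVP_l (x9), FLC_l (x10). The experimental constant levels are not redistributable; these values are calibrated so the inhibition products kappa11*kappa12 and kappa15*kappa16 reproduce the published positive steady state of the full network exactly (symmetric split between the paired inhibitors).",
  "units": "nM",
  "synthetic": true,
  "values": {
    "x7": 2.15185564143867,
    "x8": 1.18600624462131,
    "x9": 9.33850711092782,
    "x10": 14600.6817527999
  }
}
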