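{
  "dt": 0.1,
  "t_end": 3000,
  "sample_interval": 1,
  "seed": 1,
  "params": [],
  "reduction": {
    "m_c": 50,
    "m_e": 50,
    "lambda": 1e-06
  },
  "network": {
    "domain": "cylinder",
    "radius": 20,
    "length": 100,
    "boundary_tol": 3,
    "n_fibers": 110,
    "segments_per_fiber": 4,
    "crosslink_radius": 1
  },
  "cells": [
    {
      "center": [50, 0, 0]
    }
  ]
}
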