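{
  "source": "synthetic calibration v1: canonical energy-cascade functional forms; response-surface coefficients constructed from hyperbolic CO2 saturation and linear high-light attenuation anchored to plausible nominal canopy quantum yields (see package documentation)",
  "crop_id": "sweet potato",
  "t_A": 30,
  "t_Q": 48,
  "t_E": 33,
  "t_M": 85,
  "f_E": 1,
  "w_C": 0.44,
  "m_molar_C": 12.011,
  "cue_max": 0.625,
  "a_max": 0.93,
  "a_exponent": 1.5,
  "cqy_coeffs": [
    [0, 0, 0, 0, 0],
    [-6.75, 0.054, 0, 0, 0],
    [0.0011475, -9.18e-06, 0, 0, 0],
    [0, 0, 0, 0, 0],
    [0, 0, 0, 0, 0]
  ],
  "ppf_range": [50, 1000],
  "co2_range": [330, 1300]
}
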