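{
  "source": "synthetic calibration v1: canonical energy-cascade functional forms; response-surface coefficients constructed from hyperbolic CO2 saturation and linear high-light attenuation anchored to plausible nominal canopy quantum yields (see package documentation)",
  "crop_id": "dry bean",
  "t_A": 35,
  "t_Q": 42,
  "t_E": 40,
  "t_M": 63,
  "f_E": 0.97,
  "w_C": 0.45,
  "m_molar_C": 12.011,
  "cue_max": 0.65,
  "cue_min": 0.5,
  "a_max": 0.93,
  "a_exponent": 2,
  "cqy_coeffs": [
    [0, 0, 0, 0, 0],
    [-6.72, 0.048, 0, 0, 0],
    [0.001344, -9.6e-06, 0, 0, 0],
    [0, 0, 0, 0, 0],
    [0, 0, 0, 0, 0]
  ],
  "ppf_range": [50, 1000],
  "co2_range": [330, 1300]
}
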