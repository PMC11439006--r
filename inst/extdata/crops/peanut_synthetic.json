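{
  "source": "synthetic calibration v1: canonical energy-cascade functional forms; response-surface coefficients constructed from hyperbolic CO2 saturation and linear high-light attenuation anchored to plausible nominal canopy quantum yields (see package documentation)",
  "crop_id": "peanut",
  "t_A": 40,
  "t_Q": 65,
  "t_E": 49,
  "t_M": 104,
  "f_E": 0.49,
  "w_C": 0.5,
  "m_molar_C": 12.011,
  "cue_max": 0.65,
  "cue_min": 0.3,
  "a_max": 0.93,
  "a_exponent": 2,
  "cqy_coeffs": [
    [0, 0, 0, 0, 0],
    [-5.535, 0.041, 0, 0, 0],
    [0.00105165, -7.79e-06, 0, 0, 0],
    [0, 0, 0, 0, 0],
    [0, 0, 0, 0, 0]
  ],
  "ppf_range": [50, 1000],
  "co2_range": [330, 1300]
}
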