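{
  "R1": {
    "basis": "reduced",
    "coefficients": {
      "(Intercept)": 3.5933,
      "alpha": -0.1174,
      "beta": 0.2245,
      "alpha^2": 0.0028,
      "beta^2": -0.0347,
      "alpha:beta": -0.0061
    },
    "r.squared": 0.9996
  },
  "R2": {
    "basis": "full",
    "coefficients": {
      "(Intercept)": 1.8199,
      "alpha": -0.0425,
      "beta": 0.7983,
      "gamma": -0.0015,
      "alpha^2": 0.0018,
      "beta^2": -0.0764,
      "gamma^2": 0.1736,
      "alpha:beta": -0.0116,
      "alpha:gamma": -0.0133,
      "beta:gamma": -0.2144,
      "alpha:beta:gamma": 0.0026
    },
    "r.squared": 0.973
  },
  "R3": {
    "basis": "full",
    "coefficients": {
      "(Intercept)": 23.1037,
      "alpha": -0.9056,
      "beta": -10.7569,
      "gamma": 3.8688,
      "alpha^2": 0.0137,
      "beta^2": 17.9375,
      "gamma^2": -1.6817e-16,
      "alpha:beta": 0.0871,
      "alpha:gamma": 0.0157,
      "beta:gamma": -1.4677,
      "alpha:beta:gamma": 0.0406
    },
    "r.squared": 0.9909
  }
}
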