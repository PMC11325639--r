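{
  "kin_porewater": {
    "response": "kin",
    "route": "porewater",
    "descriptors": [
      "log_kom",
      "om",
      "ssalipid"
    ],
    "coefficients": {
      "intercept": -2.95,
      "log_kom": 1.05,
      "om": -0.016,
      "ssalipid": 0.35
    },
    "response_transform": "log10",
    "stats": {
      "n": 75,
      "r_squared": 0.974181646400741,
      "adj_r_squared": 0.973090730051476,
      "rmse": 0.242684885056793,
      "q2_loo": 0.97131743105268,
      "ccc_loo": 0.985462813830163
    },
    "domain": {
      "log_kom": [1.22, 5.23],
      "om": [0.97, 39.9],
      "ssalipid": [1.085, 3.828],
      "ssa": [0.7, 1.45],
      "lipid": [1.55, 2.64]
    },
    "provenance": "synthetic reference calibration v1; statistics refit on reference_calibration_synthetic.csv (seed 317)"
  },
  "kin_soil": {
    "response": "kin",
    "route": "soil",
    "descriptors": [
      "log_kom",
      "om",
      "ssalipid"
    ],
    "coefficients": {
      "intercept": -1.87,
      "log_kom": 0.22,
      "om": -0.018,
      "ssalipid": 0.35
    },
    "response_transform": "log10",
    "stats": {
      "n": 75,
      "r_squared": 0.820073111421993,
      "adj_r_squared": 0.81247056683419,
      "rmse": 0.255689630141312,
      "q2_loo": 0.79881314100111,
      "ccc_loo": 0.889372407857438
    },
    "domain": {
      "log_kom": [1.22, 5.23],
      "om": [0.97, 39.9],
      "ssalipid": [1.085, 3.828],
      "ssa": [0.7, 1.45],
      "lipid": [1.55, 2.64]
    },
    "provenance": "synthetic reference calibration v1; statistics refit on reference_calibration_synthetic.csv (seed 317)"
  },
  "kout_porewater": {
    "response": "kout",
    "route": "porewater",
    "descriptors": [
      "tpsa",
      "om"
    ],
    "coefficients": {
      "intercept": -1.87,
      "tpsa": 0.033,
      "om": 0.023
    },
    "response_transform": "log10",
    "stats": {
      "n": 75,
      "r_squared": 0.908994222931512,
      "adj_r_squared": 0.906466284679609,
      "rmse": 0.260468514869583,
      "q2_loo": 0.900818674008882,
      "ccc_loo": 0.948099190810375
    },
    "domain": {
      "tpsa": [0, 50.9],
      "om": [0.97, 39.9]
    },
    "provenance": "synthetic reference calibration v1; statistics refit on reference_calibration_synthetic.csv (seed 317)"
  },
  "kout_soil": {
    "response": "kout",
    "route": "soil",
    "descriptors": [
      "tpsa",
      "om",
      "ssalipid"
    ],
    "coefficients": {
      "intercept": -2.24,
      "tpsa": 0.026,
      "om": 0.019,
      "ssalipid": 0.27
    },
    "response_transform": "log10",
    "stats": {
      "n": 75,
      "r_squared": 0.902075740892024,
      "adj_r_squared": 0.897938096140982,
      "rmse": 0.255376558783288,
      "q2_loo": 0.890698284579376,
      "ccc_loo": 0.942609401987228
    },
    "domain": {
      "tpsa": [0, 50.9],
      "om": [0.97, 39.9],
      "ssalipid": [1.085, 3.828],
      "ssa": [0.7, 1.45],
      "lipid": [1.55, 2.64]
    },
    "provenance": "synthetic reference calibration v1; statistics refit on reference_calibration_synthetic.csv (seed 317)"
  },
  "kd_porewater": {
    "response": "log_kd",
    "route": "none",
    "descriptors": [
      "log_dow",
      "om"
    ],
    "coefficients": {
      "intercept": -0.9,
      "log_dow": 0.62,
      "om": 0.022
    },
    "response_transform": "log10",
    "stats": {
      "n": 75,
      "r_squared": 0.768511794920974,
      "adj_r_squared": 0.762081567002112,
      "rmse": 0.64791424959152,
      "q2_loo": 0.748317268743578,
      "ccc_loo": 0.857622072217653
    },
    "domain": {
      "log_dow": [1.69, 6.63],
      "om": [0.97, 39.9]
    },
    "provenance": "synthetic reference calibration v1; statistics refit on reference_calibration_synthetic.csv (seed 317)"
  }
}
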