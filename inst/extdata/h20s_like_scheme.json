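{
  "kcat_A": {
    "value": 1,
    "unit": "s^-1"
  },
  "kcat_B": {
    "value": 0.5,
    "unit": "s^-1"
  },
  "km_0": {
    "value": 60,
    "unit": "uM"
  },
  "km_A": {
    "value": 60,
    "unit": "uM"
  },
  "km_B": {
    "value": 10,
    "unit": "uM"
  },
  "K_AU": {
    "value": 0.01,
    "unit": "uM^-1"
  },
  "K_BU": {
    "value": 40,
    "unit": "uM^-1"
  },
  "K_AL": {
    "value": 0.005,
    "unit": "uM^-1"
  },
  "K_BL": {
    "value": 53.00171988288,
    "unit": "uM^-1"
  },
  "K_BI": {
    "value": 0,
    "unit": "uM^-1"
  },
  "K_AI": {
    "value": 0,
    "unit": "uM^-1"
  },
  "L_U": {
    "value": 3.10852142323413e-06,
    "unit": "dimensionless"
  },
  "L_L": {
    "value": 4.01928217987019e-05,
    "unit": "dimensionless"
  },
  "n": {
    "value": 3,
    "unit": "sites"
  },
  "m": {
    "value": 0,
    "unit": "sites"
  },
  "sigma_A": {
    "value": 1,
    "unit": "dimensionless"
  },
  "sigma_B": {
    "value": 1,
    "unit": "dimensionless"
  },
  "temperature_K": {
    "value": 310.15,
    "unit": "K"
  }
}
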