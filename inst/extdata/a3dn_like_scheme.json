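{
  "kcat_A": {
    "value": 1.8,
    "unit": "s^-1"
  },
  "kcat_B": {
    "value": 1.8,
    "unit": "s^-1"
  },
  "km_0": {
    "value": 120,
    "unit": "uM"
  },
  "km_A": {
    "value": 120,
    "unit": "uM"
  },
  "km_B": {
    "value": 30,
    "unit": "uM"
  },
  "K_AU": {
    "value": 0.01,
    "unit": "uM^-1"
  },
  "K_BU": {
    "value": 20,
    "unit": "uM^-1"
  },
  "K_AL": {
    "value": 0.025,
    "unit": "uM^-1"
  },
  "K_BL": {
    "value": 50,
    "unit": "uM^-1"
  },
  "K_BI": {
    "value": 2,
    "unit": "uM^-1"
  },
  "K_AI": {
    "value": 0,
    "unit": "uM^-1"
  },
  "L_U": {
    "value": 0.0400023529624907,
    "unit": "dimensionless"
  },
  "L_L": {
    "value": 0.1,
    "unit": "dimensionless"
  },
  "n": {
    "value": 2,
    "unit": "sites"
  },
  "m": {
    "value": 1,
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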