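{
  "groups": ["CN(A-)", "CN(A+)", "CI"],
  "n": [211, 228, 88],
  "continuous": {
    "age": {"mean": [69.72, 71.67, 72.11], "sd": [7.61, 6.53, 6.39]},
    "education": {"mean": [15.97, 15.92, 15.81], "sd": [2.57, 2.32, 2.69]}
  },
  "categorical": {
    "sex_female": {"count": [111, 126, 43], "proportion": [0.526, 0.553, 0.489]},
    "race_nhw": {"count": [190, 209, 82], "proportion": [0.900, 0.917, 0.932]},
    "apoe4_carrier": {"count": [52, 94, 50], "proportion": [0.248, 0.414, 0.575]}
  }
}
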