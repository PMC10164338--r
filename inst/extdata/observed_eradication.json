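{
  "comment": "Observed fraction of eradicated tumors per treatment group of the three efficacy studies (eradicated / evaluable).",
  "groups": [
    {"study": 1, "compound": "Rs1", "dose_mgkg": 100, "eradicated": 1, "n": 9},
    {"study": 1, "compound": "Rs2", "dose_mgkg": 25, "eradicated": 9, "n": 9},
    {"study": 1, "compound": "Rs2", "dose_mgkg": 100, "eradicated": 8, "n": 9},
    {"study": 1, "compound": "Rs3", "dose_mgkg": 20, "eradicated": 6, "n": 9},
    {"study": 2, "compound": "Rs1", "dose_mgkg": 10, "eradicated": 0, "n": 10},
    {"study": 2, "compound": "Rs1", "dose_mgkg": 50, "eradicated": 1, "n": 10},
    {"study": 2, "compound": "Rs1", "dose_mgkg": 200, "eradicated": 3, "n": 9},
    {"study": 3, "compound": "Rs1", "dose_mgkg": 25, "eradicated": 8, "n": 10},
    {"study": 3, "compound": "Rs1", "dose_mgkg": 50, "eradicated": 8, "n": 9},
    {"study": 3, "compound": "Rs1", "dose_mgkg": 100, "eradicated": 10, "n": 10}
  ]
}
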