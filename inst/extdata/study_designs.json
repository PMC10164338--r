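{
  "fraction_dose_gy": 2,
  "fractions_per_week": 5,
  "studies": [
    {
      "study": 1, "weeks": 6, "horizon_day": 80,
      "arms": [
        {"label": "vehicle", "compound": "", "dose_mgkg": 0, "conc_ug_ml": 0, "n": 9, "radiation": false},
        {"label": "RT", "compound": "", "dose_mgkg": 0, "conc_ug_ml": 0, "n": 9, "radiation": true},
        {"label": "RT+Rs1_100", "compound": "Rs1", "dose_mgkg": 100, "conc_ug_ml": 1, "n": 9, "radiation": true},
        {"label": "RT+Rs2_25", "compound": "Rs2", "dose_mgkg": 25, "conc_ug_ml": 2, "n": 9, "radiation": true},
        {"label": "RT+Rs2_100", "compound": "Rs2", "dose_mgkg": 100, "conc_ug_ml": 5, "n": 9, "radiation": true},
        {"label": "RT+Rs3_20", "compound": "Rs3", "dose_mgkg": 20, "conc_ug_ml": 7, "n": 9, "radiation": true}
      ]
    },
    {
      "study": 2, "weeks": 1, "horizon_day": 60,
      "arms": [
        {"label": "vehicle", "compound": "", "dose_mgkg": 0, "conc_ug_ml": 0, "n": 10, "radiation": false},
        {"label": "RT", "compound": "", "dose_mgkg": 0, "conc_ug_ml": 0, "n": 10, "radiation": true},
        {"label": "RT+Rs1_10", "compound": "Rs1", "dose_mgkg": 10, "conc_ug_ml": 1, "n": 10, "radiation": true},
        {"label": "RT+Rs1_50", "compound": "Rs1", "dose_mgkg": 50, "conc_ug_ml": 2, "n": 10, "radiation": true},
        {"label": "RT+Rs1_200", "compound": "Rs1", "dose_mgkg": 200, "conc_ug_ml": 9, "n": 10, "radiation": true, "horizon": 120}
      ]
    },
    {
      "study": 3, "weeks": 6, "horizon_day": 80,
      "arms": [
        {"label": "RT", "compound": "", "dose_mgkg": 0, "conc_ug_ml": 0, "n": 10, "radiation": true},
        {"label": "RT+Rs1_25", "compound": "Rs1", "dose_mgkg": 25, "conc_ug_ml": 5, "n": 10, "radiation": true},
        {"label": "RT+Rs1_50", "compound": "Rs1", "dose_mgkg": 50, "conc_ug_ml": 6, "n": 10, "radiation": true},
        {"label": "RT+Rs1_100", "compound": "Rs1", "dose_mgkg": 100, "conc_ug_ml": 7, "n": 10, "radiation": true}
      ]
    }
  ]
}
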