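{
  "dataset": {
    "cohort": {
      "n_patients": 2691,
      "prevalence": 0.19,
      "n_continuous": 18,
      "n_binary": 9,
      "feature_correlation": 0.2,
      "n_informative": 10,
      "target_auc": 0.8,
      "calibration_tolerance": 0.005,
      "missing_fraction": 0.0,
      "seed": 20210715
    }
  },
  "preprocessing": "impute",
  "classifiers": ["logistic", "gnb", "lda", "random_forest"],
  "internal_seed": 0,
  "regimens": ["bootstrap500", "split5050", "split7030", "kfold10", "repeated10x10", "loo"],
  "n_seeds": 100,
  "comparison_method": "hanley_mcneil",
  "feature_selection": "off"
}
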