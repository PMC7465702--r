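subject,smr_lda,smr_svm,smr_ensemble,act_lda,act_svm,act_ensemble,fes_lda,fes_svm,fes_ensemble
S01,56.29,56.31,59.17,64.04,65.45,69.51,46.29,50.52,48.03
S02,74.31,73.97,76.03,70.23,67.99,73.94,53.71,63.18,58.71
S03,74.28,74.68,76.44,69.30,68.07,70.26,60.00,66.67,62.50
S04,84.06,81.92,83.62,66.40,67.50,70.15,55.05,54.38,53.55
S05,67.90,64.92,67.50,58.75,63.07,64.24,54.85,60.23,55.83
S06,67.23,65.51,68.04,70.27,73.64,76.59,53.33,62.73,61.74
S07,75.48,78.23,79.11,66.52,70.27,73.91,58.64,59.85,60.91
S08,75.00,74.50,78.00,70.20,70.02,71.43,73.00,72.18,74.00
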