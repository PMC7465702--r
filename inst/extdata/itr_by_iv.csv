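subject,before_no_fes,before_yes_fes,before_average,after_no_fes,after_yes_fes,after_average,grand
S01,13.12,12.71,12.91,12.87,13.03,12.95,12.93
S02,11.81,14.13,12.97,12.24,13.47,12.86,12.91
S03,10.80,12.39,11.60,14.03,9.53,11.78,11.69
S04,11.68,15.91,13.79,14.96,14.03,14.50,14.14
S05,11.88,10.69,11.29,10.47,12.95,11.71,11.50
S06,13.29,10.10,11.70,13.29,13.20,13.25,12.47
S07,10.52,10.10,10.31,9.40,12.03,10.71,10.51
S08,13.47,10.52,12.00,11.10,14.03,12.56,12.28
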