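subject,before_no_fes,before_yes_fes,before_average,after_no_fes,after_yes_fes,after_average,grand
S01,55.0,45.0,50.0,60.0,50.0,55.0,55.0
S02,50.0,30.0,40.0,70.0,60.0,65.0,65.0
S03,30.0,55.0,42.5,35.0,55.0,45.0,45.0
S04,55.0,40.0,47.5,70.0,55.0,62.5,62.5
S05,50.0,55.0,52.5,65.0,80.0,72.5,72.5
S06,60.0,55.0,57.5,70.0,60.0,65.0,65.0
S07,30.0,40.0,35.0,55.0,45.0,50.0,50.0
S08,65.0,40.0,52.5,70.0,35.0,52.5,52.5
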