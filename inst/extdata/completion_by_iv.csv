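subject,before_no_fes,before_yes_fes,before_average,after_no_fes,after_yes_fes,after_average,grand
S01,71.7,49.2,60.4,70.8,50.0,60.4,60.4
S02,57.5,39.2,48.3,75.0,48.3,61.7,55.0
S03,44.2,62.5,53.3,23.3,62.1,42.7,48.0
S04,55.8,49.2,52.5,80.0,54.2,67.1,59.8
S05,58.3,72.5,65.4,70.0,80.8,75.4,70.4
S06,73.3,50.0,61.7,72.5,55.8,64.2,62.9
S07,40.0,43.3,41.7,60.0,45.4,52.7,47.2
S08,46.7,61.7,54.2,45.0,65.0,55.0,54.6
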