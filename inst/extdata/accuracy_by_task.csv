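subject,grasping,opening,no_fes_average,keep,stop,yes_fes_average,grand
S01,60.0,55.0,57.5,50.0,45.0,47.5,52.5
S02,65.0,55.0,60.0,35.0,55.0,45.0,52.5
S03,30.0,35.0,32.5,50.0,60.0,55.0,43.8
S04,40.0,85.0,62.5,15.0,80.0,47.5,55.0
S05,70.0,45.0,57.5,90.0,45.0,67.5,62.5
S06,70.0,60.0,65.0,60.0,55.0,57.5,61.3
S07,35.0,50.0,42.5,75.0,10.0,42.5,42.5
S08,65.0,70.0,67.5,65.0,10.0,37.5,52.5
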