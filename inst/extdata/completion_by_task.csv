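subject,grasping,opening,no_fes_average,keep,stop,yes_fes_average,grand
S01,71.7,70.8,71.3,31.7,68.3,50.0,60.6
S02,71.7,60.8,66.3,26.7,70.0,48.3,57.3
S03,38.3,29.2,33.8,40.0,84.2,62.1,47.9
S04,42.5,93.3,67.9,13.3,95.0,54.2,61.0
S05,78.3,50.0,64.2,90.0,71.7,80.8,72.5
S06,73.3,72.5,72.9,52.5,59.2,55.8,64.4
S07,45.0,55.0,50.0,68.3,22.5,45.4,47.7
S08,65.0,90.0,77.5,51.7,40.0,45.8,61.7
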