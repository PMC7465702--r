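question,estimate,standard_error
Mental Demand,3.5,1.4516
Temporal Demand,3.125,1.574773
Performance,-4.25,1.485044
Effort,0.25,1.346291
Frustration,6.25,1.644797
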