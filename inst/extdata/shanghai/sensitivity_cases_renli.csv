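case_id,operability,recovery,operational_effect,implementation_efficiency
1,0.61,0.13,0.13,0.13
2,0.43,0.07,0.07,0.43
3,0.25,0.25,0.25,0.25
4,0.31,0.07,0.31,0.31
5,0.34,0.19,0.25,0.22
6,0.29,0.29,0.13,0.29
7,0.23,0.06,0.14,0.57
8,0.43,0.07,0.43,0.07
9,0.52,0.06,0.19,0.23
10,0.57,0.06,0.06,0.31
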