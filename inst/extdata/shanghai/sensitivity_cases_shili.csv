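case_id,air_access,rail_access,road_access,hospital_km,beds
1,0.04,0.04,0.44,0.04,0.44
2,0.04,0.24,0.24,0.24,0.24
3,0.08,0.08,0.28,0.28,0.28
4,0.07,0.07,0.36,0.07,0.43
5,0.13,0.17,0.25,0.12,0.33
6,0.13,0.13,0.13,0.13,0.48
7,0.03,0.25,0.26,0.29,0.17
8,0.11,0.16,0.23,0.28,0.22
9,0.27,0.09,0.47,0.11,0.06
10,0.12,0.12,0.52,0.12,0.12
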