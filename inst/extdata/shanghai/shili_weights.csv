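criterion,weight,rank
air_access,0.06,4
rail_access,0.08,3
road_access,0.17,2
hospital_km,0.02,5
beds,0.67,1
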