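criterion,weight,rank
operability,0.57,1
recovery,0.06,4
operational_effect,0.14,3
implementation_efficiency,0.23,2
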