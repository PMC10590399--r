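id,name,operability,recovery,operational_effect,implementation_efficiency
national-cec,National Convention and Exhibition Center (Shanghai),VH,VH,MH,H
sniec,Shanghai New International Expo Centre,MH,ML,MH,VH
luwan-gym,Luwan Gymnasium,MH,MH,M,M
jingan-sc,Jing'an Sports Center,MH,MH,VH,M
siscec,Shanghai International Sourcing Convention and Exhibition Center,H,L,MH,H
wanti-gym,Shanghai Wanti Gymnasium,MH,MH,VH,ML
jiangwan-sc,Jiangwan Sports Center,MH,M,M,M
huangxing-park,Huangxing Sports Park,L,ML,MH,M
yuanshen-gym,Yuanshen Gymnasium,H,H,VH,ML
sports-palace,Shanghai Sports Palace,MH,L,H,ML
dongfang-sc,Dongfang Sports Center,H,M,H,ML
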