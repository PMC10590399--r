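id,name,closeness,rank
national-cec,National Convention and Exhibition Center (Shanghai),0.949398156,1
siscec,Shanghai International Sourcing Convention and Exhibition Center,0.860039008,2
sniec,Shanghai New International Expo Centre,0.833905844,3
jingan-sc,Jing'an Sports Center,0.785615886,4
luwan-gym,Luwan Gymnasium,0.768748131,5
jiangwan-sc,Jiangwan Sports Center,0.765861257,6
yuanshen-gym,Yuanshen Gymnasium,0.750361649,7
dongfang-sc,Dongfang Sports Center,0.745970649,8
wanti-gym,Shanghai Wanti Gymnasium,0.722281782,9
sports-palace,Shanghai Sports Palace,0.710431418,10
huangxing-park,Huangxing Sports Park,0.117826508,11
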