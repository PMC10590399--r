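id,name,category,closeness,rank
chongming-gym,Chongming Gymnasium,gymnasium,0.027,21
baoshan-gym,Baoshan Gymnasium,gymnasium,0.046,15
new-jiading-gym,New Jiading Gymnasium,gymnasium,0.045,18
sports-palace,Shanghai Sports Palace,gymnasium,0.155,10
jingan-sc,Jing'an Sports Center,gymnasium,0.202,4
yuanshen-gym,Yuanshen Gymnasium,gymnasium,0.157,9
luwan-gym,Luwan Gymnasium,gymnasium,0.213,3
wanti-gym,Shanghai Wanti Gymnasium,gymnasium,0.190,6
minhang-gym,Minhang Gymnasium,gymnasium,0.103,12
songjiang-gym,Songjiang Gymnasium,gymnasium,0.047,14
baogang-gym,Baogang Gymnasium,gymnasium,0.049,13
jiading-gym,Jiading Gymnasium,gymnasium,0.042,19
jiangwan-sc,Jiangwan Sports Center,gymnasium,0.169,7
huangxing-park,Huangxing Sports Park,gymnasium,0.158,8
caolu-sc,Caolu Sports Center,gymnasium,0.046,16
dongfang-sc,Dongfang Sports Center,gymnasium,0.138,11
fengxian-gym,Fengxian Gymnasium,gymnasium,0.032,20
jinshan-gym,Jinshan Gymnasium,gymnasium,0.015,22
auto-exhibition,Shanghai Automobile Exhibition Center,exhibition centre,0.045,17
national-cec,National Convention and Exhibition Center (Shanghai),exhibition centre,0.808,1
sniec,Shanghai New International Expo Centre,exhibition centre,0.296,2
siscec,Shanghai International Sourcing Convention and Exhibition Center,exhibition centre,0.199,5
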