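prison_id,n,n_below_lod,p25,p75,median
P1,16,12,0.050,0.132,0.050
P2,73,16,0.112,0.323,0.194
P3,5,3,0.050,0.175,0.050
P4,15,2,0.132,0.292,0.214
P5,11,3,0.050,0.240,0.187
P6,30,6,0.115,0.380,0.166
P7,32,7,0.105,0.275,0.170
P8,46,22,0.050,0.328,0.106
P9,19,9,0.050,0.252,0.120
P10,26,5,0.117,0.492,0.206
P11,26,14,0.050,0.301,0.050
P12,10,4,0.050,0.315,0.198
P13,35,15,0.050,0.229,0.139
P14,28,11,0.050,0.244,0.129
P15,35,10,0.050,0.246,0.154
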