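prison_id,capacity,staff,duration_minutes,pct_gt10,pct_gt25,pct_gt246,maximum,pm_mean,pm_sd,ambient_mean,ambient_sd
P1,700,347,8635,40,16,0,64,11.2,9.4,6.6,6.9
P2,1000,630,8644,99,93,0,222,54.6,37.5,11.4,4.9
P3,285,112,8610,86,50,0,62,28.8,16.7,10.5,3.7
P4,230,195,8638,98,78,20,1009,135.9,189.4,5.2,11.4
P5,180,162,7301,89,70,3.1,569,48.6,62.4,9.4,4.1
P6,870,476,8641,93,63,0,132,28.5,15.8,5.9,2.6
P7,670,401,8640,97,71,0,171,36,15.1,6.4,2.2
P8,500,334,8700,94,66,0,198,31.7,16.2,22.8,6.2
P9,249,198,8642,87,45,0,162,23.4,13.5,5.3,1.4
P10,103,123,8642,81,55,0.1,272,49.2,48.6,5.7,2.1
P11,500,257,8701,84,57,0.1,335,32,20.8,11.5,6.0
P12,784,352,8645,68,39,0,111,19.8,12.1,12.6,5.0
P13,630,368,8627,94,69,0,142,35.3,21.0,5.3,1.6
P14,712,452,8704,87,69,0.1,466,31.1,18.8,6.5,4.7
P15,553,370,8661,40,7,0,125,10.5,8.7,7.7,5.5
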