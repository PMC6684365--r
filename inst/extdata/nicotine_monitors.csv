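prison_id,monitor_id,concentration,duration_minutes,field_blank,duplicate_of,tampered,contemporaneous
P1,M01,0.349,8635,false,,false,false
P2,M02a,0.637,8644,false,,false,true
P2,M02b,0.546,8644,false,M02a,false,true
P3,M03,,8610,false,,true,true
P4,M04,1.651,8638,false,,false,true
P5,M05,0.608,7301,false,,false,true
P6,M06,0.436,8641,false,,false,true
P7,M07,0.159,8640,false,,false,true
P8,M08,0.323,8700,false,,false,true
P9,M09,0.169,8642,false,,false,true
P10,M10,0.546,8642,false,,false,true
P11,M11,0.101,8701,false,,false,false
P12,M12a,0.137,8645,false,,false,true
P12,M12b,0.230,8645,false,M12a,false,true
P13,M13,<LOD,8627,false,,false,true
P14,M14,0.319,8704,false,,false,true
P15,M15,<LOD,8661,false,,false,true
BLANK,FB1,<LOD,8640,true,,false,false
BLANK,FB2,<LOD,8640,true,,false,false
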