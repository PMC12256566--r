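"dose_Gy","netOD_R","netOD_G","netOD_B"
0,0,0,0
0.5,0.0411622276029056,0.027027027027027,0.0148883374689826
1,0.07981220657277,0.0531400966183575,0.0295566502463054
2,0.150442477876106,0.102803738317757,0.058252427184466
3,0.213389121338912,0.149321266968326,0.0861244019138756
5,0.320754716981132,0.234042553191489,0.13953488372093
7,0.40893470790378,0.309236947791165,0.190045248868778
9,0.482649842271293,0.376425855513308,0.237885462555066
11,0.545189504373178,0.436823104693141,0.283261802575107
13,0.598915989159892,0.491408934707904,0.326359832635983
16,0.666666666666667,0.564102564102564,0.387096774193548
20,0.739130434782609,0.647058823529412,0.461538461538462
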