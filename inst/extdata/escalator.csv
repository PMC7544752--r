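generation,length_mm,velocity_mm_min,clearance_time_s
6,9,0.74,730
7,7.6,0.5,1642
8,6.4,0.33,2805
9,5.4,0.22,4278
10,4.6000000000000005,0.15,6118
11,3.9000000000000004,0.1,8458
12,3.3000000000000003,0.07,11287
13,2.7,0.05,14527
14,2.3000000000000003,0.03,19127
15,2,0.02,25127
16,1.6500000000000001,0.01,35027
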