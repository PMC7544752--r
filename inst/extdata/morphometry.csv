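generation,length_cm,diameter_cm,branching_angle_deg,gravity_angle_deg,airway_count,mucus_velocity_mm_min
1,12,1.8,35,45,1,5.5
2,4.76,1.22,35,45,2,3.8
3,1.9,0.83,35,45,4,2.6
4,0.72,0.56,35,45,8,1.6
5,1.2,0.45,35,45,16,1
6,0.9,0.35,35,45,32,0.74
7,0.76,0.28,35,45,64,0.5
8,0.64,0.23,35,45,128,0.33
9,0.54,0.186,35,45,256,0.22
10,0.46,0.154,35,45,512,0.15
11,0.39,0.13,35,45,1024,0.1
12,0.33,0.109,35,45,2048,0.07
13,0.27,0.095,35,45,4096,0.05
14,0.23,0.082,35,45,8192,0.03
15,0.2,0.074,35,45,16384,0.02
16,0.165,0.066,35,45,32768,0.01
17,0.141,0.06,35,45,65536,NA
18,0.117,0.054,35,45,131072,NA
19,0.099,0.05,35,45,262144,NA
20,0.083,0.047,35,45,524288,NA
21,0.07,0.045,35,45,1048576,NA
22,0.059,0.043,35,45,2097152,NA
23,0.05,0.041,35,45,4194304,NA
24,0.042,0.041,35,45,8388608,NA
25,0.036,0.041,35,45,16777216,NA
26,0.031,0.041,35,45,33554432,NA
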