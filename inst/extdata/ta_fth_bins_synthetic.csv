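bin_low,bin_high,fraction
0,10,0.3125
10,20,0.27
20,30,0.1625
30,40,0.09
40,50,0.055
50,60,0.0375
60,70,0.03
70,80,0.0225
80,90,0.02
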