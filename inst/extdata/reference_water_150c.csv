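time_min,temp_c,measured_pct,predicted_pct
4,150,9.17,9.18
6,150,6.40,6.30
8,150,4.72,4.44
10,150,3.57,3.60
12,150,2.38,2.75
14,150,2.07,2.24
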