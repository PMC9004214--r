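postal_prefix,rio_score,health_region_code
P0A,78,13
P3E,45,13
P7B,52,14
P0T,88,14
K1A,5,11
M5V,0,7
L8P,12,4
N2L,18,3
K0H,46,10
N0G,58,2
L0K,41,12
M4C,2,7
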