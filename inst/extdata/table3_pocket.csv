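region,res_a,num_a,res_b,num_b
TM3,A,169,S,149
TM3,I,172,V,152
TM3,A,173,G,153
TM3,Y,176,Y,156
TM8,T,439,A,423
TM8,G,442,G,426
TM8,L,443,M,427
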