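error_class,sd_km
3,0.3
2,0.6
1,1.2
0,4.0
A,6.0
B,9.0
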