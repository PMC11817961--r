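unit_length,total_length_bp,pct_of_total
1,5107083,43.34
2,6375336,35.06
3,3604197,20.23
4,201908,0.90
5,55195,0.20
6,88128,0.27
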