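quantity,value
examined_bp,7849381805
total_ssrs,973129
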