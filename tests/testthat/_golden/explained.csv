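component,explained
1,0.684305
2,0.160502
3,0.112906
4,0.0258442
5,0.0164432
6,5.07391e-31
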