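category,dominance,n_evaluated,n_significant
Structural,0,13,0
Signaling,0.294118,17,5
Energy,0.50074,8,4
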