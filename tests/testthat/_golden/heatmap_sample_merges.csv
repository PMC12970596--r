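step,left,right,height
1,-5,-6,3
2,-1,-2,4.15331
3,-4,1,5.12348
4,-3,2,6.18466
5,3,4,11.1766
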