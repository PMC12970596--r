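sample_id,PC1,PC2,PC3,PC4,PC5,PC6
CTRL_1,-4.6688,0.263015,-0.390488,0.459087,0.967781,7.01586e-15
CTRL_2,-4.90924,3.79375,-0.358478,-1.30535,-0.301805,-1.17327e-16
CTRL_3,-5.03735,-0.30326,3.89727,0.510479,-0.500551,2.1574e-16
EXP_1,4.63898,4.13147,0.613114,1.201,0.0962762,1.04522e-16
EXP_2,4.53424,0.0853371,2.51015,-1.12951,1.01165,-2.28545e-16
EXP_3,4.6688,-0.263015,0.390488,-0.459087,-0.967781,6.98791e-15
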