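sample_id,group,comp1,comp2
CTRL_1,CTRL,-4.56773,-1.58601
CTRL_2,CTRL,-4.77855,-1.33357
CTRL_3,CTRL,-4.88396,2.83721
EXP_1,EXP,4.77855,-1.09316
EXP_2,EXP,4.67314,1.45979
EXP_3,EXP,4.77855,-0.284251
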