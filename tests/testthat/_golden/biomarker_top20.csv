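rank,index_id,display_name,category,p_value,auc,cohens_d,power,log2fc
1,cardiolipin_fraction,Cardiolipin Fraction,Structural,0,1,-Inf,1,-0.30746
2,ce_fraction,CE/Total Index,Structural,0,1,-Inf,1,-0.31877
3,double_bond_index,Double Bond Index,Structural,0,1,Inf,1,0.0377762
4,mono_poly,Mono/Poly Ratio,Structural,0,1,Inf,1,0.0445735
5,saturation_index,Saturation Index,Structural,0,1,-Inf,1,-0.140788
6,structural_energetic,Structural/Energetic,Structural,0,1,-Inf,1,-0.962198
7,lyso_pl,(LPC+LPE)/PL Index,Signaling,0,1,-Inf,1,-1
8,bmp_fraction,BMP Fraction,Signaling,0,1,-Inf,1,-0.303631
9,cer_sm,Cer/SM Index,Signaling,0,1,Inf,1,0.678072
10,ceramide_fraction,Ceramide Fraction,Signaling,0,1,Inf,1,0.377583
11,ether_fraction,Ether Lipid Fraction,Signaling,0,1,-Inf,1,-0.353376
12,ferroptosis,Ferroptosis Susceptibility Index,Signaling,0,1,-Inf,1,-0.329548
13,lpc_pc,LPC/PC Index,Signaling,0,1,-Inf,1,-1
14,lpe_pe,LPE/PE Index,Signaling,0,1,-Inf,1,-1
15,lyso_o_matched,Lyso-O/PL-O (matched),Signaling,0,1,-Inf,1,-1
16,lyso_p_matched,Lyso-P/PL-P (matched),Signaling,0,1,-Inf,1,-1
17,lyso_matched,Lyso/PL (matched),Signaling,0,1,-Inf,1,-1
18,omega6_omega3,n-6/n-3 Index,Signaling,0,1,Inf,1,0.472812
19,acylcarnitine_fraction,Acylcarnitine Fraction,Energy,0,1,-Inf,1,-0.303808
20,dg_tg,DG/TG Index,Energy,0,1,-Inf,1,-1
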