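enzyme,substrates,products,note
SGMS1,Cer+PC,SM+DG,sphingomyelin synthase transfers phosphocholine from PC to ceramide
SGMS2,Cer+PC,SM+DG,plasma-membrane sphingomyelin synthase
SMPD1,SM,Cer,acid sphingomyelinase hydrolyses sphingomyelin to ceramide
CerS2,FA,Cer,ceramide synthase N-acylates the sphingoid base (acyl-CoA proxied by FA)
DGAT1,DG+FA,TG,diacylglycerol acyltransferase completes triacylglycerol (acyl-CoA proxied by FA)
DGAT2,DG+FA,TG,ER diacylglycerol acyltransferase
PNPLA2,TG,DG+FA,adipose triglyceride lipase initiates lipolysis
LIPE,DG,FA,hormone-sensitive lipase hydrolyses diacylglycerol
LPL,TG,DG+FA,lipoprotein lipase hydrolyses circulating triacylglycerol
PLA2G4A,PC,LPC+FA,cytosolic phospholipase A2 releases sn-2 fatty acid from PC
LPCAT3,LPC+FA,PC,lysophosphatidylcholine acyltransferase reacylates LPC
PEMT,PE,PC,phosphatidylethanolamine N-methyltransferase
SCD1,FA&db==0,FA&db==1,stearoyl-CoA desaturase converts saturated to monounsaturated fatty acids
SOAT1,Chol+FA,CE,sterol O-acyltransferase esterifies cholesterol
CPT1A,FA,CAR,carnitine palmitoyltransferase forms acylcarnitines
PLD1,PC,PA,phospholipase D hydrolyses PC to phosphatidic acid
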