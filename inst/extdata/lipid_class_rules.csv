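class_id,class_name,n_acyl_positions,backbone,linkage,lineage,charge,curvature,function_terms,component_terms
PC,diacylglycerophosphocholines,2,glycerol,ester,Glycerophospholipids>Glycerophosphocholines>Diacylglycerophosphocholines,positive_zwitterion,neutral,membrane component,endoplasmic reticulum;plasma membrane
PC O-,1-alkyl-2-acylglycerophosphocholines,2,glycerol,ether_O,Glycerophospholipids>Glycerophosphocholines>1-alkyl-2-acylglycerophosphocholines,positive_zwitterion,neutral,membrane component,plasma membrane
PC P-,1-alkenyl-2-acylglycerophosphocholines,2,glycerol,ether_P,Glycerophospholipids>Glycerophosphocholines>1-alkenyl-2-acylglycerophosphocholines,positive_zwitterion,neutral,membrane component,plasma membrane
LPC,monoacylglycerophosphocholines,1,glycerol,ester,Glycerophospholipids>Glycerophosphocholines>Monoacylglycerophosphocholines,positive_zwitterion,positive,lipid-mediated signaling;membrane component,endoplasmic reticulum
PE,diacylglycerophosphoethanolamines,2,glycerol,ester,Glycerophospholipids>Glycerophosphoethanolamines>Diacylglycerophosphoethanolamines,positive_zwitterion,negative,membrane component,mitochondrion;endoplasmic reticulum
PE O-,1-alkyl-2-acylglycerophosphoethanolamines,2,glycerol,ether_O,Glycerophospholipids>Glycerophosphoethanolamines>1-alkyl-2-acylglycerophosphoethanolamines,positive_zwitterion,negative,membrane component,plasma membrane
PE P-,1-alkenyl-2-acylglycerophosphoethanolamines,2,glycerol,ether_P,Glycerophospholipids>Glycerophosphoethanolamines>1-alkenyl-2-acylglycerophosphoethanolamines,positive_zwitterion,negative,membrane component,plasma membrane
LPE,monoacylglycerophosphoethanolamines,1,glycerol,ester,Glycerophospholipids>Glycerophosphoethanolamines>Monoacylglycerophosphoethanolamines,positive_zwitterion,positive,lipid-mediated signaling,endoplasmic reticulum
PS,diacylglycerophosphoserines,2,glycerol,ester,Glycerophospholipids>Glycerophosphoserines>Diacylglycerophosphoserines,negative,neutral,membrane component,plasma membrane
LPS,monoacylglycerophosphoserines,1,glycerol,ester,Glycerophospholipids>Glycerophosphoserines>Monoacylglycerophosphoserines,negative,positive,lipid-mediated signaling,plasma membrane
PG,diacylglycerophosphoglycerols,2,glycerol,ester,Glycerophospholipids>Glycerophosphoglycerols>Diacylglycerophosphoglycerols,negative,neutral,membrane component,mitochondrion
LPG,monoacylglycerophosphoglycerols,1,glycerol,ester,Glycerophospholipids>Glycerophosphoglycerols>Monoacylglycerophosphoglycerols,negative,positive,membrane component,mitochondrion
BMP,bis(monoacylglycero)phosphates,2,glycerol,ester,Glycerophospholipids>Glycerophosphoglycerols>Bis(monoacylglycero)phosphates,negative,neutral,membrane component,lysosome
PI,diacylglycerophosphoinositols,2,glycerol,ester,Glycerophospholipids>Glycerophosphoinositols>Diacylglycerophosphoinositols,negative,neutral,membrane component;lipid-mediated signaling,endoplasmic reticulum;Golgi apparatus
LPI,monoacylglycerophosphoinositols,1,glycerol,ester,Glycerophospholipids>Glycerophosphoinositols>Monoacylglycerophosphoinositols,negative,positive,lipid-mediated signaling,endoplasmic reticulum
PA,diacylglycerophosphates,2,glycerol,ester,Glycerophospholipids>Glycerophosphates>Diacylglycerophosphates,negative,negative,lipid-mediated signaling;membrane component,endoplasmic reticulum
LPA,monoacylglycerophosphates,1,glycerol,ester,Glycerophospholipids>Glycerophosphates>Monoacylglycerophosphates,negative,positive,lipid-mediated signaling,endoplasmic reticulum
MG,monoacylglycerols,1,glycerol,ester,Glycerolipids>Monoradylglycerols>Monoacylglycerols,neutral,positive,lipid storage;lipid-mediated signaling,lipid droplet
DG,diacylglycerols,2,glycerol,ester,Glycerolipids>Diradylglycerols>Diacylglycerols,neutral,negative,lipid-mediated signaling;lipid storage,endoplasmic reticulum;lipid droplet
DG O-,1-alkyl-2-acylglycerols,2,glycerol,ether_O,Glycerolipids>Diradylglycerols>1-alkyl-2-acylglycerols,neutral,negative,lipid storage,lipid droplet
TG,triacylglycerols,3,glycerol,ester,Glycerolipids>Triradylglycerols>Triacylglycerols,neutral,neutral,lipid storage,lipid droplet
TG O-,1-alkyl-2-3-diacylglycerols,3,glycerol,ether_O,Glycerolipids>Triradylglycerols>1-alkyl-2-3-diacylglycerols,neutral,neutral,lipid storage,lipid droplet
Cer,ceramides,2,sphingoid,ester,Sphingolipids>Ceramides,neutral,negative,lipid-mediated signaling;membrane component,endoplasmic reticulum
SM,sphingomyelins,2,sphingoid,ester,Sphingolipids>Phosphosphingolipids>Sphingomyelins,positive_zwitterion,neutral,membrane component,plasma membrane
HexCer,hexosylceramides,2,sphingoid,ester,Sphingolipids>Neutral glycosphingolipids>Hexosylceramides,neutral,neutral,membrane component,Golgi apparatus;plasma membrane
Hex2Cer,dihexosylceramides,2,sphingoid,ester,Sphingolipids>Neutral glycosphingolipids>Dihexosylceramides,neutral,neutral,membrane component,plasma membrane
SHexCer,sulfatides,2,sphingoid,ester,Sphingolipids>Acidic glycosphingolipids>Sulfatides,negative,neutral,membrane component,plasma membrane
GM3,GM3 gangliosides,2,sphingoid,ester,Sphingolipids>Acidic glycosphingolipids>Gangliosides,negative,positive,membrane component;lipid-mediated signaling,plasma membrane
SPH,sphingoid bases,1,sphingoid,ester,Sphingolipids>Sphingoid bases,positive_zwitterion,positive,lipid-mediated signaling,endoplasmic reticulum
S1P,sphingoid base 1-phosphates,1,sphingoid,ester,Sphingolipids>Sphingoid bases>Sphingoid base 1-phosphates,negative,positive,lipid-mediated signaling,plasma membrane
CE,cholesteryl esters,1,sterol,ester,Sterol lipids>Steryl esters>Cholesteryl esters,neutral,neutral,lipid storage,lipid droplet
FA,fatty acids,1,none,ester,Fatty acyls>Fatty acids,negative,positive,lipid-mediated signaling,endoplasmic reticulum
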