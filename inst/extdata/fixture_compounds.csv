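name,smiles
lindane,ClC1C(Cl)C(Cl)C(Cl)C(Cl)C1Cl
aldrin,ClC1=C(Cl)C2(Cl)C3C4CC(C=C4)C3C1(Cl)C2(Cl)Cl
2-2-dichloropropanoic acid,CC(Cl)(Cl)C(=O)O
chlordimeform,CN(C)C=Nc1ccc(Cl)cc1C
iodopropynyl butylcarbamate,CCCCNC(=O)OCC#CI
dimethoate,CNC(=O)CSP(=S)(OC)OC
diflubenzuron,Fc1cccc(F)c1C(=O)NC(=O)Nc1ccc(Cl)cc1
2-(digeranylamino)ethanol,OCCN(CC=C(C)CCC=C(C)C)CC=C(C)CCC=C(C)C
benzocaine,CCOC(=O)c1ccc(N)cc1
allethrin,CC1=C(CC=C)C(=O)CC1OC(=O)C1C(C=C(C)C)C1(C)C
hexazinone,CN(C)C1=NC(=O)N(C2CCCCC2)C(=O)N1C
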