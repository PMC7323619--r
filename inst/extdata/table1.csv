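substrate_id,entry,smiles_synthetic,structure_confidence,conditions,sear_absent
t1e1,1,c1ccc2[nH]ccc2c1,low,"CO, EtOH, Pd(OAc)2, Cu(OAc)2, KOAc, DMF, KI, 100 C, 13 h",1
t1e2,2,c1ccc2occc2c1,low,"CO, Pd(OAc)2, Cu(OAc)2, PivOH, mesitylene, 120 C, 6 h",0
t1e3,3,c1ccc(cc1)C(=O)N,low,"Cu(OAc)2, Pd(OAc)2, K2CO3, DMF, 60 C, 0.6 h",0
t1e4,4,c1ccc(cc1)c1ccccn1,low,"PhCOCO2H, Pd(OAc)2, K2S2O8, MeCN, 25 C, 16 h",0
t1e5,5,c1ccc(cc1)C(=O)Nc1ccccc1,low,"PhSi(OMe)3, Pd(OAc)2, AgF, dioxane, 80 C, 16 h",0
t1e6,6,c1ccc2c(c1)cc[nH]2,low,"Ph-CHO, Pd(OAc)2, TBHP, toluene, 110 C, 5 h",0
t1e7,7,Cc1ccccc1C(=O)N,low,"Ph-CHO, Pd(OAc)2, xylene, O2, 120 C, 24 h",0
t1e8,8,c1ccc(cc1)N(=O)=O,low,"PhCOCO2H, Pd(OAc)2, Ag2CO3, DMF, 120 C, 24 h",0
t1e9,9,COc1ccccc1,low,"H-COOPh, Pd(OAc)2, I2, K2CO3, DMF, 100 C, 12 h",0
t1e10,10,c1ccc(cc1)C(=O)O,low,"PhB(OH)2, Pd(OAc)2, TEMPO, phen, DMAc, O2, 100 C, 48 h",0
t1e11,11,c1ccc(cc1)C#N,low,"benzene, Pd(OAc)2, O2, HOAc, DMA, 130 C, 20 h",0
t1e12,12,Cc1ccc(cc1)C(=O)N,low,"Pd(OAc)2, CuCO3, dioxane, DMSO, 140 C, 16 h",0
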