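substrate_id,entry,smiles_synthetic,structure_confidence,conditions,sear_absent
t3e1,1,c1ccc(cc1)C(=O)Nc1ccccn1,low,"Pd(OAc)2, TBHP, toluene, 120 C, 6 h",0
t3e2,2,Cc1ccc(cc1)S(=O)(=O)N,low,"Pd(OAc)2, TBHP, DCE, 80 C, 16 h",0
t3e3,3,COc1cccc(c1)C(=O)N,low,"Pd(OAc)2, TBHP, toluene, TFA, 40 C, 3 h",0
t3e4,4,c1ccc(cc1)C(=O)NC,low,"Pd(OAc)2, toluene, TBHP, 110 C, 5 h",1
t3e5,5,c1ccc2c(c1)oc1ccccc21,low,"Pd(OAc)2, 1,4-dioxane, AcOH, DMSO, TBHP, 110 C, 24 h",0
t3e6,6,c1ccc(cc1)Oc1ccccc1,low,"Ag2CO3, Pd(OAc)2, NaOAc, CO, 1,4-dioxane, 130 C, 18 h",0
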