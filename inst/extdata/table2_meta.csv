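substrate_id,entry,pred_mec,delta_kcal,smiles_synthetic,structure_confidence
t2e1,1,SEAR,6.0,c1ccoc1,low
t2e2,2,SEAR,6.0,c1ccsc1,low
t2e3,3,PA,-2.0,c1cc2ccccc2o1,low
t2e4,4,PA,-2.0,c1ccc2[nH]ccc2c1,low
t2e5,5,PA,NA,c1ccncc1,low
t2e6,6,AMBIGUOUS,2.5,c1ccc2sccc2c1,low
t2e7,7,PA,NA,c1cncnc1,low
t2e8,8,PA,-2.0,Cn1ccc2ccccc21,low
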