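entry,gibbs_hartree,pd_c_angstrom,relative_stability,predicted_mechanism,reported_mechanism,stable,anomaly_flag
1,-355.5652,2.3005,3.0777,PA/SEAR,PA/SEAR,1,0
2,-355.5577,2.3778,-1.6369,PA,PA,1,0
3,-355.5626,2.1345,1.4558,PA/SEAR,PA/SEAR,1,0
4,NA,NA,NA,PA,PA,0,0
5,355.5717,7.1781,2.2326,SEAR,SEAR,1,1
6,-355.5254,2.1680,-21.9298,PA,PA,1,0
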