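name	series	parent_mz	rt_min	product_ions	batch_id
PGD2	DEH	351	12.56	315;271;233;203;189	t2_deh
PGE2	DEH	351	12.23	333;315;271;235;189;175;109	t2_deh
PGH2	DEH	351	12.23	333;315;271;235;217;189;175;113;109	t2_deh
PGF1a	F1	355	11.83	337;319;311;301;293;275;265;249;237;211;195	t2_f1
8-iso PGF1a	F1	355	11.34	337;319;311;293;275;265;249;237;219;211;183	t2_f1
9b-PGF1a	F1	355	11.36	337;319;311;301;293;275;265;237;211;183;167	t2_f1
8-iso 9b-PGF1a	F1	355	11.44	337;319;311;293;275;265;219;211;183	t2_f1
9b,11b-PGF1a	F1	355	11.99	337;319;311;301;293;275;265;237;219;211;183	t2_f1
PGF2a	F2	353	11.73	335;317;309;291;273;263;247;209;193;171;165	t2_f2
ent-PGF2a	F2	353	11.71	335;317;309;291;273;247;209;193;191;171;165	t2_f2
11b PGF2a	F2	353	11.48	335;317;309;291;273;247;209;193;173;165;111	t2_f2
15(R)-PGF2a	F2	353	11.89	335;317;309;291;273;247;209;193;191;171;165	t2_f2
8-iso PGF2a	F2	353	11.31	335;307;309;291;273;247;209;193;181;171;165	t2_f2
5-trans PGF2a	F2	353	11.60	335;317;309;291;273;247;209;193;171;165;111	t2_f2
8-iso 15(R)-PGF2a	F2	353	11.39	335;317;309;291;273;263;247;209;193;171;165	t2_f2
9b-PGF2a	F2	353	11.22	335;317;309;291;273;255;247;193;173;171;165	t2_f2
PGF3a	F3	351	11.26	333;315;307;289;271;245;219;209;193;191;165	t2_f3
8-iso PGF3a	F3	351	10.83	333;315;307;289;271;245;219;209;193;191;171	t2_f3
2,3-Dinor-11b-PGF2a	metabolite	325	10.67	261;245;227;219;173;163;153;145;137;113;107	t2_metab
19(R)-hydroxy PGF2a	hydroxylated	369	9.19	351;333;325;315;307;263;235;209;193;171;165	t2_ohf
20-hydroxy PGF2a	hydroxylated	369	9.13	351;333;325;315;307;263;209;193;181;171;165	t2_ohf
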