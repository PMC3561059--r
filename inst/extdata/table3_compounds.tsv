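name	series	parent_mz	rt_min	product_ions	batch_id
Class 1 (RT 11.24)	F1	355	11.24	319;311;301;293;275;265;249;219;211;179;157	worm
CePGF1	F1	355	11.70	319;311;301;293;275;265;237;223;211;195;157	worm
Class 1 (RT 11.85)	F1	355	11.85	311;301;293;237;195;193;183;179;157;153	worm
Class 1 (RT 12.08)	F1	355	12.08	311;301;293;275;265;211;195;167;157	worm
Class 1 (RT 12.31)	F1	355	12.31	337;319;311;293;275;265;187;179;157;153	worm
CePGF2	F2	353	11.73	309;291;273;263;247;209;193;171;167;137	worm
CePGF2b	F2	353	12.09	309;291;273;263;255;247;219;209;193;171;113	worm
Class 3 (RT 11.34)	F3	351	11.34	315;307;289;275;249;205;193;191;167;153;139	worm
Class 3 (RT 11.90)	F3	351	11.90	307;289;263;249;193;191;185;147;137;115;109	worm
Class 3 (RT 12.51)	F3	351	12.51	333;289;271;261;245;223;193;191;163	worm
Class 3 (RT 12.62)	F3	351	12.62	289;271;245;223;219;201;193;183;149;113;107	worm
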