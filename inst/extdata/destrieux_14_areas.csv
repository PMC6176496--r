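roi_id,roi_name,hemisphere,area
1,lh.G_and_S_frontomargin,L,LVPF
2,lh.G_and_S_transv_frontopol,L,LVPF
3,lh.G_front_inf-Opercular,L,LVPF
4,lh.G_front_inf-Orbital,L,LVPF
5,lh.G_front_inf-Triangul,L,LVPF
6,lh.G_orbital,L,LVPF
7,lh.G_rectus,L,LVPF
8,lh.Lat_Fis-ant-Horizont,L,LVPF
9,lh.Lat_Fis-ant-Vertical,L,LVPF
10,lh.S_orbital_lateral,L,LVPF
11,lh.S_orbital_med-olfact,L,LVPF
12,lh.S_orbital-H_Shaped,L,LVPF
13,lh.S_suborbital,L,LVPF
14,lh.S_front_inf,L,LVPF
15,lh.G_front_middle,L,LDPF
16,lh.G_front_sup,L,LDPF
17,lh.S_front_middle,L,LDPF
18,lh.S_front_sup,L,LDPF
19,lh.G_and_S_paracentral,L,LC
20,lh.G_and_S_subcentral,L,LC
21,lh.G_postcentral,L,LC
22,lh.G_precentral,L,LC
23,lh.S_central,L,LC
24,lh.S_postcentral,L,LC
25,lh.S_precentral-inf-part,L,LC
26,lh.S_precentral-sup-part,L,LC
27,lh.G_Ins_lg_and_S_cent_ins,L,LT
28,lh.G_insular_short,L,LT
29,lh.G_oc-temp_lat-fusifor,L,LT
30,lh.G_oc-temp_med-Parahip,L,LT
31,lh.G_temp_sup-G_T_transv,L,LT
32,lh.G_temp_sup-Lateral,L,LT
33,lh.G_temp_sup-Plan_polar,L,LT
34,lh.G_temp_sup-Plan_tempo,L,LT
35,lh.G_temporal_inf,L,LT
36,lh.G_temporal_middle,L,LT
37,lh.Lat_Fis-post,L,LT
38,lh.Pole_temporal,L,LT
39,lh.S_circular_insula_ant,L,LT
40,lh.S_circular_insula_inf,L,LT
41,lh.S_circular_insula_sup,L,LT
42,lh.S_collat_transv_ant,L,LT
43,lh.S_oc-temp_lat,L,LT
44,lh.S_temporal_inf,L,LT
45,lh.S_temporal_sup,L,LT
46,lh.S_temporal_transverse,L,LT
47,lh.G_pariet_inf-Angular,L,LP
48,lh.G_pariet_inf-Supramar,L,LP
49,lh.G_parietal_sup,L,LP
50,lh.G_precuneus,L,LP
51,lh.S_interm_prim-Jensen,L,LP
52,lh.S_intrapariet_and_P_trans,L,LP
53,lh.S_subparietal,L,LP
54,lh.G_and_S_occipital_inf,L,LO
55,lh.G_cuneus,L,LO
56,lh.G_occipital_middle,L,LO
57,lh.G_occipital_sup,L,LO
58,lh.G_oc-temp_med-Lingual,L,LO
59,lh.Pole_occipital,L,LO
60,lh.S_calcarine,L,LO
61,lh.S_collat_transv_post,L,LO
62,lh.S_oc_middle_and_Lunatus,L,LO
63,lh.S_oc_sup_and_transversal,L,LO
64,lh.S_occipital_ant,L,LO
65,lh.S_oc-temp_med_and_Lingual,L,LO
66,lh.S_parieto_occipital,L,LO
67,lh.G_and_S_cingul-Ant,L,LCing
68,lh.G_and_S_cingul-Mid-Ant,L,LCing
69,lh.G_and_S_cingul-Mid-Post,L,LCing
70,lh.G_cingul-Post-dorsal,L,LCing
71,lh.G_cingul-Post-ventral,L,LCing
72,lh.G_subcallosal,L,LCing
73,lh.S_cingul-Marginalis,L,LCing
74,lh.S_pericallosal,L,LCing
75,rh.G_and_S_frontomargin,R,RVPF
76,rh.G_and_S_transv_frontopol,R,RVPF
77,rh.G_front_inf-Opercular,R,RVPF
78,rh.G_front_inf-Orbital,R,RVPF
79,rh.G_front_inf-Triangul,R,RVPF
80,rh.G_orbital,R,RVPF
81,rh.G_rectus,R,RVPF
82,rh.Lat_Fis-ant-Horizont,R,RVPF
83,rh.Lat_Fis-ant-Vertical,R,RVPF
84,rh.S_orbital_lateral,R,RVPF
85,rh.S_orbital_med-olfact,R,RVPF
86,rh.S_orbital-H_Shaped,R,RVPF
87,rh.S_suborbital,R,RVPF
88,rh.S_front_inf,R,RVPF
89,rh.G_front_middle,R,RDPF
90,rh.G_front_sup,R,RDPF
91,rh.S_front_middle,R,RDPF
92,rh.S_front_sup,R,RDPF
93,rh.G_and_S_paracentral,R,RC
94,rh.G_and_S_subcentral,R,RC
95,rh.G_postcentral,R,RC
96,rh.G_precentral,R,RC
97,rh.S_central,R,RC
98,rh.S_postcentral,R,RC
99,rh.S_precentral-inf-part,R,RC
100,rh.S_precentral-sup-part,R,RC
101,rh.G_Ins_lg_and_S_cent_ins,R,RT
102,rh.G_insular_short,R,RT
103,rh.G_oc-temp_lat-fusifor,R,RT
104,rh.G_oc-temp_med-Parahip,R,RT
105,rh.G_temp_sup-G_T_transv,R,RT
106,rh.G_temp_sup-Lateral,R,RT
107,rh.G_temp_sup-Plan_polar,R,RT
108,rh.G_temp_sup-Plan_tempo,R,RT
109,rh.G_temporal_inf,R,RT
110,rh.G_temporal_middle,R,RT
111,rh.Lat_Fis-post,R,RT
112,rh.Pole_temporal,R,RT
113,rh.S_circular_insula_ant,R,RT
114,rh.S_circular_insula_inf,R,RT
115,rh.S_circular_insula_sup,R,RT
116,rh.S_collat_transv_ant,R,RT
117,rh.S_oc-temp_lat,R,RT
118,rh.S_temporal_inf,R,RT
119,rh.S_temporal_sup,R,RT
120,rh.S_temporal_transverse,R,RT
121,rh.G_pariet_inf-Angular,R,RP
122,rh.G_pariet_inf-Supramar,R,RP
123,rh.G_parietal_sup,R,RP
124,rh.G_precuneus,R,RP
125,rh.S_interm_prim-Jensen,R,RP
126,rh.S_intrapariet_and_P_trans,R,RP
127,rh.S_subparietal,R,RP
128,rh.G_and_S_occipital_inf,R,RO
129,rh.G_cuneus,R,RO
130,rh.G_occipital_middle,R,RO
131,rh.G_occipital_sup,R,RO
132,rh.G_oc-temp_med-Lingual,R,RO
133,rh.Pole_occipital,R,RO
134,rh.S_calcarine,R,RO
135,rh.S_collat_transv_post,R,RO
136,rh.S_oc_middle_and_Lunatus,R,RO
137,rh.S_oc_sup_and_transversal,R,RO
138,rh.S_occipital_ant,R,RO
139,rh.S_oc-temp_med_and_Lingual,R,RO
140,rh.S_parieto_occipital,R,RO
141,rh.G_and_S_cingul-Ant,R,RCing
142,rh.G_and_S_cingul-Mid-Ant,R,RCing
143,rh.G_and_S_cingul-Mid-Post,R,RCing
144,rh.G_cingul-Post-dorsal,R,RCing
145,rh.G_cingul-Post-ventral,R,RCing
146,rh.G_subcallosal,R,RCing
147,rh.S_cingul-Marginalis,R,RCing
148,rh.S_pericallosal,R,RCing
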