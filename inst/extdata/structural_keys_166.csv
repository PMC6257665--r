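bit,type,param,threshold,name
1,elem,C,1,carbon
2,elem,C,4,carbon_ge4
3,elem,C,8,carbon_ge8
4,elem,C,12,carbon_ge12
5,elem,C,16,carbon_ge16
6,elem,N,1,nitrogen
7,elem,N,2,nitrogen_ge2
8,elem,N,3,nitrogen_ge3
9,elem,N,4,nitrogen_ge4
10,elem,O,1,oxygen
11,elem,O,2,oxygen_ge2
12,elem,O,3,oxygen_ge3
13,elem,O,4,oxygen_ge4
14,elem,S,1,sulfur
15,elem,S,2,sulfur_ge2
16,elem,P,1,phosphorus
17,elem,F,1,fluorine
18,elem,F,2,fluorine_ge2
19,elem,F,3,fluorine_ge3
20,elem,Cl,1,chlorine
21,elem,Cl,2,chlorine_ge2
22,elem,Br,1,bromine
23,elem,I,1,iodine
24,halogen,,1,halogen
25,halogen,,2,halogen_ge2
26,halogen,,3,halogen_ge3
27,hetero,,1,heteroatom
28,hetero,,2,heteroatom_ge2
29,hetero,,4,heteroatom_ge4
30,hetero,,6,heteroatom_ge6
31,atoms,,10,atoms_ge10
32,atoms,,15,atoms_ge15
33,atoms,,20,atoms_ge20
34,atoms,,25,atoms_ge25
35,bonds,,10,bonds_ge10
36,bonds,,15,bonds_ge15
37,bonds,,20,bonds_ge20
38,bonds,,25,bonds_ge25
39,rings,,1,ring
40,rings,,2,rings_ge2
41,rings,,3,rings_ge3
42,rings,,4,rings_ge4
43,aroRings,,1,aromatic_ring
44,aroRings,,2,aromatic_rings_ge2
45,aroRings,,3,aromatic_rings_ge3
46,ringSize,3,1,ring3
47,ringSize,4,1,ring4
48,ringSize,5,1,ring5
49,ringSize,6,1,ring6
50,ringSize,7,1,ring7
51,ringSize,8,1,ring8
52,elemRing,N,1,N_in_ring
53,elemRing,N,2,N_in_ring_ge2
54,elemRing,O,1,O_in_ring
55,elemRing,O,2,O_in_ring_ge2
56,elemRing,S,1,S_in_ring
57,aroElem,N,1,aromatic_N
58,aroElem,O,1,aromatic_O
59,aroElem,S,1,aromatic_S
60,aroElem,C,6,aromatic_C_ge6
61,degree,3,1,branch3
62,degree,3,2,branch3_ge2
63,degree,3,3,branch3_ge3
64,degree,4,1,branch4
65,degree,4,2,branch4_ge2
66,charge,+,1,cation
67,charge,-,1,anion
68,charge,any,2,multi_charge
69,multiBond,=,1,double_bond
70,multiBond,=,2,double_bonds_ge2
71,multiBond,=,3,double_bonds_ge3
72,multiBond,#,1,triple_bond
73,path,C-C,1,CC
74,path,C=C,1,alkene
75,path,C#C,1,alkyne
76,path,C-N,1,amine
77,path,C=N,1,imine
78,path,C#N,1,nitrile
79,path,C-O,1,C_O
80,path,C=O,1,carbonyl
81,path,C-S,1,thioether
82,path,C=S,1,thiocarbonyl
83,path,N-N,1,hydrazine
84,path,N=N,1,azo
85,path,N-O,1,N_O
86,path,N=O,1,nitroso
87,path,N-S,1,N_S
88,path,O-S,1,O_S
89,path,O=S,1,S_oxide
90,path,O-O,1,peroxide
91,path,C-F,1,C_F
92,path,C-Cl,1,C_Cl
93,path,C-Br,1,C_Br
94,path,C-I,1,C_I
95,path,c:c,1,aro_CC
96,path,c:n,1,aro_CN
97,path,c:o,1,aro_CO
98,path,c:s,1,aro_CS
99,path,n:n,1,aro_NN
100,path,C-c,1,alkyl_aryl
101,path,N-c,1,aryl_N
102,path,O-c,1,aryl_O
103,path,S-c,1,aryl_S
104,path,F-c,1,aryl_F
105,path,Cl-c,1,aryl_Cl
106,path,Br-c,1,aryl_Br
107,path,I-c,1,aryl_I
108,path,c-c,1,biaryl
109,path,n-c,1,N_aryl_link
110,path,C-P,1,C_P
111,path,O-P,1,O_P
112,path,O=P,1,P_oxide
113,path,C-C-C,1,propyl
114,path,C-C-N,1,CCN
115,path,C-C-O,1,CCO
116,path,C-C=O,1,ketone_chain
117,path,N-C=O,1,amide
118,path,O-C=O,1,carboxyl
119,path,N-C=N,1,amidine
120,path,N-C-N,1,aminal
121,path,O-C-O,1,acetal
122,path,C-O-C,1,ether
123,path,C-N-C,1,sec_amine
124,path,C-S-C,1,dialkyl_sulfide
125,path,C-C-S,1,CCS
126,path,C-C=C,1,allyl
127,path,C=C-N,1,enamine
128,path,C-C-F,1,CCF
129,path,C-C-Cl,1,CCCl
130,path,C-C-c,1,phenethyl
131,path,N-C-c,1,benzylamine
132,path,O-C-c,1,benzyl_O
133,path,O=C-c,1,aryl_carbonyl
134,path,C-O-c,1,aryl_ether
135,path,C-N-c,1,aryl_sec_amine
136,path,c:c:c,1,aro_path2
137,path,c:c:n,1,aro_CCN
138,path,c:n:c,1,aro_CNC
139,path,C-c:c,1,ortho_alkyl
140,path,N-c:c,1,ortho_amino
141,path,O-c:c,1,ortho_oxy
142,path,Cl-c:c,1,ortho_chloro
143,path,O=N-O,1,nitro
144,path,O=C-Cl,1,acyl_chloride
145,path,O=S=O,1,sulfone
146,path,N-S=O,1,sulfonamide
147,path,C=N-N,1,hydrazone
148,path,C-N-N,1,alkyl_hydrazine
149,path,N-C-O,1,N_C_O
150,path,N-C-S,1,N_C_S
151,path,N=C-S,1,thioamide_like
152,path,C-C#C,1,internal_alkyne
153,path,C-C#N,1,alkyl_nitrile
154,path,C-C-C-C,1,butyl
155,path,C-C-C-N,1,CCCN
156,path,C-C-C-O,1,CCCO
157,path,N-C-C-O,1,aminoalcohol
158,path,O-C-C-O,1,glycol
159,path,N-C-C-N,1,diamine
160,path,N-C-C=O,1,amide_chain
161,path,C-O-C=O,1,ester
162,path,C-N-C=O,1,N_alkyl_amide
163,path,c:c:c:c,1,aro_path3
164,path,C-c:c:c,1,aryl_chain
165,path,O-c:c:c,1,aryl_oxy_path
166,path,N-c:c:c,1,aryl_amino_path
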