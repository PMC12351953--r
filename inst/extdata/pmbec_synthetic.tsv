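	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	1	0.647481	0.659483	0.497367	0.336867	0.789751	0.582749	0.469781	0.434867	0.580341	0.683725	0.607567	0.461598	0.50828	0.339891	0.758584	0.740805	0.295881	0.083329	0.457302
C	0.647481	1	0.50507	0.271484	0.20523	0.66866	0.388414	0.769043	0.221632	0.707089	0.445649	0.242124	0.40745	0.543673	0.282173	0.790785	0.811247	0.652913	0.292035	0.336561
D	0.659483	0.50507	1	0.810871	0.3051	0.751566	0.829665	0.317525	0.672218	0.436532	0.558248	0.751584	0.707057	0.900578	0.742717	0.728211	0.862243	0.268143	0.16791	0.593008
E	0.497367	0.271484	0.810871	1	0.51765	0.478377	0.785673	0.210569	0.803548	0.375886	0.639398	0.802207	0.720434	0.719574	0.850312	0.387397	0.603991	0.18532	0.108482	0.681912
F	0.336867	0.20523	0.3051	0.51765	1	0.202614	0.384464	0.301725	0.418046	0.552319	0.759861	0.322343	0.43408	0.320913	0.445192	0.156713	0.334182	0.256408	0.102487	0.58667
G	0.789751	0.66866	0.751566	0.478377	0.202614	1	0.463359	0.330521	0.306247	0.411026	0.414952	0.479436	0.63113	0.585282	0.35441	0.800055	0.817416	0.357003	0.095883	0.295659
H	0.582749	0.388414	0.829665	0.785673	0.384464	0.463359	1	0.354265	0.924782	0.479085	0.704391	0.813866	0.463229	0.812228	0.775714	0.584221	0.690504	0.181239	0.179835	0.861619
I	0.469781	0.769043	0.317525	0.210569	0.301725	0.330521	0.354265	1	0.224733	0.894879	0.5451	0.173617	0.257215	0.413767	0.255109	0.487655	0.578406	0.603486	0.396928	0.439981
K	0.434867	0.221632	0.672218	0.803548	0.418046	0.306247	0.924782	0.224733	1	0.352327	0.656989	0.827453	0.379442	0.638155	0.754239	0.367523	0.482254	0.105054	0.111836	0.852531
L	0.580341	0.707089	0.436532	0.375886	0.552319	0.411026	0.479085	0.894879	0.352327	1	0.775438	0.283435	0.427231	0.522787	0.403924	0.480829	0.675877	0.637705	0.33993	0.609242
M	0.683725	0.445649	0.558248	0.639398	0.759861	0.414952	0.704391	0.5451	0.656989	0.775438	1	0.581725	0.470672	0.547545	0.547499	0.43489	0.613551	0.309879	0.154407	0.827543
N	0.607567	0.242124	0.751584	0.802207	0.322343	0.479436	0.813866	0.173617	0.827453	0.283435	0.581725	1	0.424368	0.554378	0.562456	0.461013	0.511533	0.092165	0.049787	0.58966
P	0.461598	0.40745	0.707057	0.720434	0.43408	0.63113	0.463229	0.257215	0.379442	0.427231	0.470672	0.424368	1	0.67103	0.64686	0.399171	0.698117	0.438035	0.155607	0.400442
Q	0.50828	0.543673	0.900578	0.719574	0.320913	0.585282	0.812228	0.413767	0.638155	0.522787	0.547545	0.554378	0.67103	1	0.844512	0.659188	0.870235	0.358231	0.34907	0.675727
R	0.339891	0.282173	0.742717	0.850312	0.445192	0.35441	0.775714	0.255109	0.754239	0.403924	0.547499	0.562456	0.64686	0.844512	1	0.355948	0.604287	0.229262	0.257588	0.750541
S	0.758584	0.790785	0.728211	0.387397	0.156713	0.800055	0.584221	0.487655	0.367523	0.480829	0.43489	0.461013	0.399171	0.659188	0.355948	1	0.845892	0.315404	0.17173	0.389009
T	0.740805	0.811247	0.862243	0.603991	0.334182	0.817416	0.690504	0.578406	0.482254	0.675877	0.613551	0.511533	0.698117	0.870235	0.604287	0.845892	1	0.523472	0.286906	0.562993
V	0.295881	0.652913	0.268143	0.18532	0.256408	0.357003	0.181239	0.603486	0.105054	0.637705	0.309879	0.092165	0.438035	0.358231	0.229262	0.315404	0.523472	1	0.37933	0.2164
W	0.083329	0.292035	0.16791	0.108482	0.102487	0.095883	0.179835	0.396928	0.111836	0.33993	0.154407	0.049787	0.155607	0.34907	0.257588	0.17173	0.286906	0.37933	1	0.242303
Y	0.457302	0.336561	0.593008	0.681912	0.58667	0.295659	0.861619	0.439981	0.852531	0.609242	0.827543	0.58966	0.400442	0.675727	0.750541	0.389009	0.562993	0.2164	0.242303	1
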