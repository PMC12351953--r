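	PC1	PC2	PC3	PC4	PC5	PC6	PC7	PC8	PC9
A	0.766663	-1.272147	0.898227	-0.032124	0.202161	-0.649175	1.558552	1.141542	-1.282562
C	1.001014	-0.791408	-0.576415	-1.36107	-0.351881	0.030292	0.191684	0.991136	-1.257804
D	-1.00771	-0.728597	0.130432	0.089284	0.741653	0.518054	0.007064	-0.980673	0.445291
E	-1.00771	-0.069091	0.335923	1.338856	-0.709137	1.52399	-0.220972	1.764981	-0.751941
F	1.10145	1.175032	0.161773	1.952127	-1.335989	-1.092002	-1.390288	-0.656748	0.310203
G	0.030131	-1.960642	-0.227059	-0.143718	0.423774	1.404452	0.577387	0.086823	-0.145094
H	-0.907273	0.288443	1.005313	0.012366	-0.791881	0.215533	-0.325812	-0.421322	-0.343055
I	1.670588	0.614573	-0.218325	-1.344718	1.411848	1.079719	-0.288358	-0.132568	-1.849556
K	-1.141624	0.660473	1.391486	0.658844	-0.420654	0.934867	0.92744	0.166428	-0.995488
L	1.436237	0.614573	-0.193988	-0.332539	0.64149	0.689074	0.805901	0.099963	0.503815
M	0.800141	0.522773	0.847879	0.654656	0.315427	-1.480432	1.42719	-0.038927	0.918185
N	-1.00771	-0.656124	1.595825	0.8794	-0.76496	-0.308438	-0.607984	0.089287	-0.214086
P	-0.371614	-0.689945	-1.204287	1.177029	1.540454	0.569333	0.619164	-0.482152	0.312216
Q	-1.00771	0.061361	-0.3586	-0.304541	0.629034	-1.37024	1.426094	-0.500236	1.511034
R	-1.342497	0.77643	-0.247779	0.699269	0.08859	-0.865134	-1.299286	-1.614101	1.849451
S	-0.103784	-1.262483	0.338276	-1.303124	0.271094	0.517037	-1.026959	-0.382885	-0.859216
T	-0.070305	-0.607809	-0.362763	-0.462727	0.664589	0.747249	-1.322107	-0.508355	0.186889
V	1.570152	-0.030439	-2.169978	-0.52261	0.088661	0.372859	-1.678834	2.586658	1.594962
W	-0.137263	2.090611	-2.005432	-1.931427	-2.923507	-1.286919	-0.00215	-1.326235	-0.189371
Y	-0.271178	1.264416	0.859492	0.276766	0.279235	-1.550119	0.622275	0.117385	0.256128
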