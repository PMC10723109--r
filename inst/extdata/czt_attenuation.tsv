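# Linear attenuation coefficients for Cd0.9Zn0.1Te, density 5.9 g/cm^3
# Generated by tools/make_attenuation.R (Klein-Nishina incoherent term with
# incoherent-scattering-function correction; parametric photoelectric and
# coherent fits anchored to published CZT values). Units: keV, cm^-1.
# molecular_density_cm3: 1.509946e+22
energy_keV	photoelectric_cm1	incoherent_cm1	coherent_cm1
50	102.4	0.707697	0.801337
52.774	87.0863	0.707128	0.724571
55.701	74.0664	0.706292	0.655179
58.791	62.9908	0.705186	0.59242
62.052	53.5726	0.703805	0.535679
65.494	45.5623	0.702148	0.484371
69.127	38.7496	0.700212	0.437977
72.962	32.9549	0.697996	0.396022
77.009	28.0276	0.6955	0.358092
81.281	23.8365	0.692723	0.323791
85.789	20.2729	0.689668	0.292782
90.548	17.2414	0.686334	0.264737
95.571	14.6633	0.682725	0.239379
100	12.8	0.679487	0.219986
100.873	12.3971	0.678479	0.216448
106.468	10.1749	0.672093	0.195718
112.374	8.36679	0.665503	0.176971
118.607	6.89318	0.658717	0.160022
125.187	5.68971	0.651741	0.144693
132.131	4.70541	0.644584	0.130834
139.46	3.89881	0.637257	0.118303
147.196	3.23658	0.629766	0.106972
155.362	2.69189	0.622122	0.0967244
163.98	2.24317	0.614335	0.08746
173.076	1.87281	0.606417	0.0790829
182.677	1.56656	0.598376	0.0715079
192.81	1.31289	0.590224	0.0646588
200	1.16592	0.584638	0.0603912
203.505	1.10239	0.581537	0.0584658
214.794	0.927393	0.571876	0.0528656
226.709	0.78166	0.562183	0.0478019
239.285	0.660081	0.552468	0.0432232
252.558	0.558476	0.542742	0.0390833
266.568	0.473405	0.533013	0.0353397
281.354	0.402062	0.523293	0.0319549
296.962	0.342112	0.513587	0.028894
313.434	0.291661	0.503907	0.0261265
330.821	0.249119	0.494259	0.023624
349.172	0.213188	0.48465	0.0213612
368.541	0.182786	0.475087	0.0193152
388.984	0.157018	0.465577	0.0174651
410.562	0.135139	0.456124	0.0157922
433.336	0.11653	0.446735	0.0142796
450	0.105185	0.440212	0.0133092
457.374	0.100674	0.437413	0.0129118
482.745	0.0871411	0.428163	0.0116751
509.523	0.075571	0.418989	0.0105568
511	0.075	0.418499	0.0105
537.787	0.0656615	0.409849	0.00954566
567.619	0.05716	0.400791	0.00863134
599.105	0.0498539	0.391821	0.00780461
632.338	0.0435643	0.382939	0.00705706
667.415	0.0381405	0.374149	0.0063811
704.437	0.0334556	0.365453	0.0057699
743.513	0.0294019	0.356851	0.00521724
784.756	0.0258886	0.348347	0.00471752
828.288	0.0228383	0.339941	0.00426566
874.234	0.0201858	0.331636	0.00385708
922.729	0.0178753	0.323432	0.00348763
973.913	0.0158594	0.315332	0.00315358
1027.937	0.0140976	0.307336	0.00285152
1084.958	0.0125553	0.299446	0.00257839
1145.142	0.011203	0.291663	0.00233143
1208.665	0.0100153	0.283989	0.00210811
1275.711	0.00897065	0.276425	0.00190619
1346.476	0.0080502	0.268973	0.00172361
1421.166	0.00723794	0.261633	0.00155852
1500	0.00652	0.254408	0.00140924
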