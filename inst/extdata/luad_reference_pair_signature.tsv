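pair	coef	hr	hr_low	hr_high	p
RHOQ-AS1|AL359697.1	-0.7110	0.4912	0.3428	0.7038	0.0001
AC130650.2|AC010168.2	0.2996	1.3493	0.9530	1.9103	0.0913
AC093788.1|NFYC-AS1	0.4626	1.5881	1.1392	2.2139	0.0064
AL109614.1|KDM4A-AS1	0.3157	1.3712	0.9752	1.9278	0.0694
AC016394.1|AC026356.1	-0.6480	0.5231	0.3682	0.7430	0.0003
EML4-AS1|HIF1A-AS3	-0.5189	0.5951	0.4087	0.8666	0.0068
EML4-AS1|LINC01936	0.5108	1.6666	1.1070	2.5091	0.0144
AL354989.1|DLEU1	-0.2950	0.7445	0.5161	1.0740	0.1146
GAS6-DT|KDM4A-AS1	0.3164	1.3721	0.9753	1.9304	0.0693
AF117829.1|AC004908.2	0.3163	1.3720	0.9803	1.9203	0.0652
AF117829.1|AC103591.3	0.3006	1.3507	0.9470	1.9264	0.0971
AC006017.1|AC002128.1	-0.4220	0.6557	0.4345	0.9895	0.0444
AL513327.1|AC099343.2	0.4033	1.4968	0.9742	2.2997	0.0656
AC090739.1|AC091057.1	-0.3498	0.7048	0.5006	0.9924	0.0451
PABPC4-AS1|AC104695.3	-0.4186	0.6580	0.4277	1.0122	0.0568
SAP30L-AS1|AC007546.1	0.4359	1.5463	1.1002	2.1733	0.0121
AP001628.1|AC026355.2	0.3883	1.4745	1.0179	2.1359	0.0400
AC245014.3|LINC01936	0.3581	1.4307	0.9318	2.1965	0.1016
LINC01290|AC091057.1	-0.2807	0.7553	0.5272	1.0821	0.1260
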