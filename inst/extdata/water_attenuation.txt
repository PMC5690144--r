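# quantity: attenuation
# material: water
# units: cm2_per_g
# representative values transcribed from standard reference compilations,
# log-log resampled onto a 60-node log grid (0.01-30 MeV)
energy_MeV value
0.01 5.329
0.011453396 3.61619
0.013118027 2.4539
0.015024595 1.6661
0.017208263 1.18306
0.019709304 0.840067
0.022573846 0.643701
0.025854718 0.497798
0.029612431 0.384966
0.033916289 0.325395
0.038845667 0.277647
0.044491479 0.24769
0.050957851 0.224618
0.058364042 0.208954
0.066846646 0.197263
0.076562107 0.186928
0.08768961 0.178237
0.10043438 0.17047
0.11503147 0.163434
0.13175009 0.156688
0.15089859 0.150207
0.17283012 0.143693
0.19794917 0.137462
0.22671902 0.131024
0.25967026 0.12485
0.29741061 0.118966
0.34063614 0.112908
0.39014404 0.10713
0.4468474 0.101414
0.51179201 0.0959031
0.58617563 0.0904629
0.67137013 0.0851283
0.76894676 0.0800686
0.88070514 0.0751309
1.0087064 0.0704131
1.1553114 0.0657789
1.3232238 0.0613954
1.5155406 0.0572272
1.7358086 0.0532646
1.9880902 0.0495763
2.2770383 0.046072
2.6079821 0.0428122
2.987025 0.0397831
3.4211579 0.0369972
3.9183874 0.0344072
4.4878841 0.0320577
5.1401512 0.029899
5.8872185 0.0279608
6.7428642 0.0262622
7.722869 0.0246842
8.8453073 0.0233212
10.13088 0.022095
11.603298 0.021127
13.289716 0.0202014
15.221237 0.0193427
17.433485 0.0187302
19.96726 0.018137
22.869293 0.0177828
26.193106 0.017438
30 0.0171
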