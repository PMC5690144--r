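# quantity: energy_absorption
# material: water
# units: cm2_per_g
# representative values transcribed from standard reference compilations,
# log-log resampled onto a 60-node log grid (0.01-30 MeV)
energy_MeV value
0.01 4.944
0.011453396 3.22081
0.013118027 2.09823
0.015024595 1.36686
0.017208263 0.887716
0.019709304 0.576533
0.022573846 0.377477
0.025854718 0.24739
0.029612431 0.162133
0.033916289 0.110358
0.038845667 0.0754177
0.044491479 0.0547901
0.050957851 0.0410148
0.058364042 0.0332861
0.066846646 0.0295285
0.076562107 0.0267984
0.08768961 0.025759
0.10043438 0.0254824
0.11503147 0.0261927
0.13175009 0.0269229
0.15089859 0.0276807
0.17283012 0.0286217
0.19794917 0.0295948
0.22671902 0.0303484
0.25967026 0.0310999
0.29741061 0.0318702
0.34063614 0.0323013
0.39014404 0.0327136
0.4468474 0.0328891
0.51179201 0.0329708
0.58617563 0.0328591
0.67137013 0.032533
0.76894676 0.0321662
0.88070514 0.0316122
1.0087064 0.0309752
1.1553114 0.03013
1.3232238 0.0292314
1.5155406 0.0282461
1.7358086 0.0271648
1.9880902 0.0261248
2.2770383 0.0249857
2.6079821 0.0238902
2.987025 0.0228427
3.4211579 0.0218018
3.9183874 0.0208071
4.4878841 0.0198669
5.1401512 0.0189806
5.8872185 0.0181705
6.7428642 0.0174442
7.722869 0.0167546
8.8453073 0.0161594
10.13088 0.0156183
11.603298 0.0151894
13.289716 0.0147724
15.221237 0.0143794
17.433485 0.0140986
19.96726 0.0138233
22.869293 0.0136357
26.193106 0.0134516
30 0.01327
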