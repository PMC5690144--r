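# quantity: attenuation
# material: tungsten
# units: cm2_per_g
# representative values transcribed from standard reference compilations,
# log-log resampled onto a 60-node log grid (0.01-30 MeV)
energy_MeV value
0.01 96.9
0.011453396 109.336
0.013118027 123.369
0.015024595 138.408
0.017208263 97.1953
0.019709304 68.2541
0.022573846 47.837
0.025854718 33.5193
0.029612431 23.487
0.033916289 16.4707
0.038845667 11.5513
0.044491479 8.08791
0.050957851 5.66456
0.058364042 3.98546
0.066846646 4.90682
0.076562107 6.97095
0.08768961 6.1912
0.10043438 4.39123
0.11503147 3.10747
0.13175009 2.19901
0.15089859 1.55718
0.17283012 1.11887
0.19794917 0.803933
0.22671902 0.596528
0.25967026 0.443803
0.29741061 0.330179
0.34063614 0.257749
0.39014404 0.201869
0.4468474 0.1634
0.51179201 0.1339
0.58617563 0.112338
0.67137013 0.096922
0.76894676 0.0841085
0.88070514 0.0741012
1.0087064 0.065804
1.1553114 0.0599044
1.3232238 0.0545337
1.5155406 0.0497836
1.7358086 0.0470209
1.9880902 0.0444115
2.2770383 0.0431487
2.6079821 0.0419764
2.987025 0.0408359
3.4211579 0.0406169
3.9183874 0.0404285
4.4878841 0.0407083
5.1401512 0.0411501
5.8872185 0.0418948
6.7428642 0.0430753
7.722869 0.04436
8.8453073 0.0459394
10.13088 0.0476815
11.603298 0.0496181
13.289716 0.0516333
15.221237 0.0537438
17.433485 0.0560572
19.96726 0.0584702
22.869293 0.0607275
26.193106 0.0630686
30 0.0655
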