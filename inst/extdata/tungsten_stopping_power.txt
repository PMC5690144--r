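# quantity: stopping_power
# material: tungsten
# units: MeV_cm2_per_g
# representative values transcribed from standard reference compilations,
# log-log resampled onto a 60-node log grid (0.01-30 MeV)
energy_MeV value
0.01 9
0.011453396 8.15356
0.013118027 7.38673
0.015024595 6.6922
0.017208263 6.07635
0.019709304 5.51717
0.022573846 5.00877
0.025854718 4.54715
0.029612431 4.12807
0.033916289 3.75625
0.038845667 3.41875
0.044491479 3.12214
0.050957851 2.85607
0.058364042 2.62477
0.066846646 2.4218
0.076562107 2.2368
0.08768961 2.07789
0.10043438 1.93614
0.11503147 1.81901
0.13175009 1.70897
0.15089859 1.60651
0.17283012 1.52911
0.19794917 1.45545
0.22671902 1.40185
0.25967026 1.35154
0.29741061 1.30304
0.34063614 1.27768
0.39014404 1.25426
0.4468474 1.23502
0.51179201 1.21872
0.58617563 1.21127
0.67137013 1.21777
0.76894676 1.22723
0.88070514 1.24283
1.0087064 1.26186
1.1553114 1.29134
1.3232238 1.3215
1.5155406 1.35346
1.7358086 1.39986
1.9880902 1.44785
2.2770383 1.51413
2.6079821 1.58424
2.987025 1.6576
3.4211579 1.74851
3.9183874 1.8449
4.4878841 1.94582
5.1401512 2.0492
5.8872185 2.14609
6.7428642 2.27328
7.722869 2.41247
8.8453073 2.58498
10.13088 2.78362
11.603298 3.04249
13.289716 3.32544
15.221237 3.63905
17.433485 4.02172
19.96726 4.44463
22.869293 4.89861
26.193106 5.39877
30 5.95
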