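# quantity: attenuation
# material: copper
# units: cm2_per_g
# representative values transcribed from standard reference compilations,
# log-log resampled onto a 60-node log grid (0.01-30 MeV)
energy_MeV value
0.01 215.9
0.011453396 150.91
0.013118027 105.483
0.015024595 73.7199
0.017208263 50.9163
0.019709304 35.1666
0.022573846 24.1168
0.025854718 16.5248
0.029612431 11.3228
0.033916289 7.73295
0.038845667 5.2794
0.044491479 3.61581
0.050957851 2.48182
0.058364042 1.71713
0.066846646 1.20819
0.076562107 0.853761
0.08768961 0.618749
0.10043438 0.454854
0.11503147 0.356687
0.13175009 0.279707
0.15089859 0.220085
0.17283012 0.186405
0.19794917 0.157879
0.22671902 0.140704
0.25967026 0.125924
0.29741061 0.112696
0.34063614 0.103673
0.39014404 0.0955523
0.4468474 0.0887581
0.51179201 0.0826394
0.58617563 0.0771548
0.67137013 0.0720899
0.76894676 0.0673683
0.88070514 0.0629203
1.0087064 0.0587474
1.1553114 0.0547859
1.3232238 0.0511349
1.5155406 0.0478017
1.7358086 0.0448957
1.9880902 0.0421662
2.2770383 0.0400076
2.6079821 0.0379772
2.987025 0.0360499
3.4211579 0.0346785
3.9183874 0.0333738
4.4878841 0.0324451
5.1401512 0.0316644
5.8872185 0.0311511
6.7428642 0.0309416
7.722869 0.0307815
8.8453073 0.0308702
10.13088 0.0310594
11.603298 0.0313679
13.289716 0.0316794
15.221237 0.0320087
17.433485 0.0324633
19.96726 0.0329244
22.869293 0.0332994
26.193106 0.0336776
30 0.03406
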