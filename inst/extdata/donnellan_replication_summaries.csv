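study,n,r,p,bf01,bf0plus,bf0r_57,bf0r_37
study1,235,-0.06,0.35,7.90,22.59,16825.57,39.37
study2,480,-0.01,0.90,17.36,19.24,17679.82,47.45
study3,210,0.13,0.06,2.09,1.08,50.25,1.15
study4,228,-0.10,0.15,4.21,28.58,21904.40,35.05
study5,494,0.10,0.03,1.67,0.85,134.72,1.32
study6,553,0.08,0.06,3.13,1.61,398.01,2.98
study7,311,0.02,0.72,13.21,10.32,4894.19,23.76
study8,365,0.02,0.77,14.60,11.84,7002.82,28.75
study9,197,-0.13,0.07,2.17,30.86,21755.50,28.25
studies1-4,1153,-0.03,0.31,16.17,52.21,49671.92,70.00
studies5-9,1920,0.01,0.56,29.53,20.53,31021.07,70.36
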