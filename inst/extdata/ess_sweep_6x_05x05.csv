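# field=0.5x0.5
# beam_quality=6X
# provenance=reference ESS sweep differences, calc minus meas, percent
ESSy\ESSx,0,0.4,0.5,0.6,0.7,0.8,0.9,1,1.5
0,4.06,,,,1.39,,,,-10.52
0.4,,,2.30,,0.84,0.84,-1.09,,
0.5,,2.30,2.30,2.07,0.84,0.84,-1.09,-1.16,
0.6,,,2.51,1.95,0.73,0.73,-1.20,-1.27,
0.7,3.12,,1.94,1.70,0.19,0.19,-1.72,-1.73,-11.56
0.8,,,1.94,1.70,0.19,0.19,-1.72,-1.73,
0.9,,1.04,1.04,0.81,-0.63,-0.63,-2.53,-2.54,
1,,,1.03,0.80,-0.64,-0.64,-2.55,-2.56,-12.27
1.5,-3.58,,,,-6.01,,,,-16.94
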