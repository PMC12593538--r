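# field=0.5x4
# beam_quality=6X
# provenance=reference ESS sweep differences, calc minus meas, percent
ESSy\ESSx,0,0.4,0.5,0.6,0.7,0.8,0.9,1,1.5
0,2.60,,,,-0.03,,,,-11.29
0.4,,,1.42,,-0.03,-0.03,-1.90,,
0.5,,1.42,1.42,1.18,-0.03,-0.03,-1.90,-1.96,
0.6,,,1.42,1.18,-0.03,-0.03,-1.90,-1.96,
0.7,2.65,,1.45,1.21,-0.02,-0.02,-1.90,-1.91,-11.29
0.8,,,1.45,1.21,-0.02,-0.02,-1.90,-1.91,
0.9,,1.45,1.45,1.21,-0.02,-0.02,-1.91,-1.91,
1,,,1.43,1.19,-0.04,-0.04,-1.92,-1.93,-11.30
1.5,2.69,,,,0.05,,,,-11.20
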