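# field=4x0.5
# beam_quality=6X
# provenance=reference ESS sweep differences, calc minus meas, percent
ESSy\ESSx,0,0.4,0.5,0.6,0.7,0.8,0.9,1,1.5
0,1.10,,,,1.11,,,,1.17
0.4,,,0.75,,0.76,0.76,0.77,,
0.5,,0.75,0.75,0.75,0.76,0.76,0.77,0.72,
0.6,,,0.60,0.60,0.61,0.61,0.61,0.56,
0.7,0.03,,0.03,0.03,0.01,0.01,0.01,0.02,0.07
0.8,,,0.03,0.03,0.01,0.01,0.01,0.02,
0.9,,-0.83,-0.83,-0.83,-0.84,-0.84,-0.84,-0.84,
1,,,-0.85,-0.85,-0.85,-0.85,-0.85,-0.87,-0.80
1.5,-6.11,,,,-6.09,,,,-1.55
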