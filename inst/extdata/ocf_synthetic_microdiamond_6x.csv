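# synthetic example OCF table (not a published dataset): plausible
# microDiamond-like output correction factors for a 6 MV beam, for
# demonstrating the loading, validity-filtering and interpolation workflow.
# detector=microDiamond
# beam_quality=6X
# synthetic=true
field_side_cm,ocf
0.4,1.058
0.5,1.041
0.6,1.030
0.8,1.018
1.0,1.011
1.5,1.005
2.0,1.002
3.0,1.001
4.0,1.000
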