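# kind=measured
# beam_quality=6X
# msr_side_cm=4
# provenance=reference measured dataset, HD-MLC TrueBeam, microDiamond, TRS-483 workflow
X\Y [cm],0.5,1.0,1.5,2.0,2.5,3.0,4.0
0.5,0.636,0.686,0.700,0.705,0.708,0.710,0.711
1,0.737,0.819,0.845,0.857,0.865,0.868,0.872
1.5,0.763,0.858,0.892,0.908,0.918,0.924,0.930
2,0.773,0.872,0.912,0.931,0.943,0.951,0.958
2.5,0.777,0.880,0.920,0.945,0.957,0.965,0.975
3,0.779,0.883,0.927,0.950,0.965,0.973,0.984
4,0.782,0.888,0.933,0.959,0.975,0.985,1.000
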