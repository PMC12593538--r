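# kind=measured
# beam_quality=6FFF
# msr_side_cm=4
# provenance=reference measured dataset, HD-MLC TrueBeam, microDiamond, TRS-483 workflow
X\Y [cm],0.5,1.0,1.5,2.0,2.5,3.0,4.0
0.5,0.662,0.705,0.718,0.723,0.726,0.727,0.729
1,0.757,0.828,0.852,0.863,0.869,0.873,0.877
1.5,0.779,0.863,0.894,0.907,0.916,0.922,0.929
2,0.787,0.875,0.910,0.929,0.938,0.946,0.955
2.5,0.792,0.882,0.920,0.940,0.953,0.960,0.972
3,0.794,0.887,0.926,0.948,0.962,0.971,0.983
4,0.797,0.893,0.934,0.958,0.973,0.984,1.000
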