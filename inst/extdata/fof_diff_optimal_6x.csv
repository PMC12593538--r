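# kind=difference_percent
# beam_quality=6X
# msr_side_cm=4
# convention=as_published
# provenance=reference calc-minus-meas differences at optimized ESS
X\Y [cm],0.5,1.0,1.5,2.0,2.5,3.0,4.0
0.5,0.2,0.4,0.2,0.1,0.1,0.0,0.0
1,0.5,0.7,0.7,0.5,0.2,0.1,0.1
1.5,0.2,0.6,0.5,0.4,0.1,0.0,-0.1
2,0.1,0.6,0.5,0.4,0.2,0.0,0.1
2.5,0.1,0.6,0.6,0.2,0.2,0.1,0.0
3,0.0,0.6,0.5,0.4,0.2,0.2,0.2
4,0.0,0.6,0.6,0.4,0.2,0.1,0.0
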