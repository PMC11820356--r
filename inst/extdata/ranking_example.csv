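# synthetic metric values reproducing one participant's published metric
# rankings over five paced frequencies:
#   amplitude 4.5/5/5.5/6/6.5, coherence 4.5/5/6/6.5/5.5, synchrony 4.5/5/6.5/6/5.5
freq,mean_amp,lf_ratio,plv
4.5,12.0,0.90,0.95
5.0,10.0,0.85,0.90
5.5,8.0,0.65,0.70
6.0,6.0,0.80,0.75
6.5,4.0,0.70,0.85
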