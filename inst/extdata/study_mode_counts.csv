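mode,tp,fn,fp,tn
cad_cross,190,10,137,175
cad_quadri,175,25,58,254
novice_without,120,80,47,265
novice_combined,158,42,38,274
experienced_without,152,48,22,290
experienced_combined,174,26,40,272
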