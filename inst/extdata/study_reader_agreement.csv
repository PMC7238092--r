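novice_mode,pp,pn,np,nn
without_cad,121,53,46,292
combined_cad,141,33,55,283
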