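reader,n_changed,direction,correct,incorrect
novice,115,4A_to_4B,44,28
novice,115,4B_to_4A,37,6
experienced,70,4A_to_4B,27,28
experienced,70,4B_to_4A,10,5
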