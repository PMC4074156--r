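{"domains":{"S1":[60,180],"S2":[260,400],"P":[420,470]},"key_residues":{"R_s1":100,"T_s2":290,"DE_s2":395}}
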