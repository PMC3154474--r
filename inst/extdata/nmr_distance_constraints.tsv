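category	OX-DNA	undamaged
intra-residue	315	432
inter-residue	112	233
cross-strand	54	118
total	481	665
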