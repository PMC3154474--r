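ensemble	class	percent
CP-TGGT	G7-O6	20
CP-TGGT	T8-O4	37
CP-TGGT	T8-O4+G7-O6	12
CP-TGGT	None	29
OX-TGGT	G7-O6	59
OX-TGGT	T8-O4	6
OX-TGGT	T8-O4+G7-O6	13
OX-TGGT	None	20
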