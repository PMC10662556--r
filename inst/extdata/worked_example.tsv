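gene	mutation_type	nucleotide_change
FAM171B	Missense	AA → AC
FAM171B	Nonsense	GG → GT
FAM171B	Missense	GG → GA
ABCA6	Missense	GG → GT
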