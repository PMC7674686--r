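# Whole-genome duplication events, keyed by the child node of the branch
# that carries them.  The two ancestral vertebrate WGDs sit on the stem
# above the vertebrate ancestor (keyed by the root node's own name); the
# teleost-specific WGD sits on the stem of the Danio+Takifugu clade.
branch	event	order
vertebrate_ancestor	WGD1	1
vertebrate_ancestor	WGD2	2
teleost_ancestor	TS_WGD	1
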