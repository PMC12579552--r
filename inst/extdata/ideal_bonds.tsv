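resname	atom1	atom2	length
*	N	CA	1.458
*	CA	C	1.525
*	C	O	1.231
*	CA	CB	1.530
*	C	N+	1.329
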