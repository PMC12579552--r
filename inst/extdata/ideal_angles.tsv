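resname	atom1	atom2	atom3	angle
*	N	CA	C	111.2
*	CA	C	O	120.8
*	N	CA	CB	110.4
*	CA	C	N+	116.2
*	O	C	N+	123.0
*	C	N+	CA+	121.7
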