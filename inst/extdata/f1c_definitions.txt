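# Haplogroup F1c control-region fixture, rooted in F1.
# F1c is diagnosed by the control-region motif 16111-16129-16304-152-249d;
# its major internal branch is defined by variant 16266.
F1
	F1c	16111,16129,16304,152,249d
		F1c1	16266
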