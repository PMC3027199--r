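# Haplogroup M9a'b nomenclature, rooted in M9.
# One node per line: depth as leading tabs, name, then comma-separated
# defining variant tokens relative to its parent; "-" marks a structural
# node with no standalone definers.
#
# Definers quoted from the published nomenclature update:
#   M9a = 14308,16234; M9a1 = 1041; M9a1a = 16316 (control region only);
#   M9a4 = 6366; M9a5 = 385,8155,12237; M9b coding diagnostic = 4491;
#   M9a1a1c1b carries 16291 and 711 (its internal subsets are delimited by
#   back mutations at those sites).
# M9a'b itself is diagnosed by the candidate screen (control-region motif
# 16223-16234-16362-153 and/or coding site 3394 or 4491), not by tree
# definers, hence "-".
# Definers for M9a1a1, M9a1a2, M9a1b, M9a1b1, M9a1a1c, M9a1a1c1 are known
# only from tree figures and are SYNTHETIC stand-ins here; edit this file to
# your nomenclature build before production use.
M9
	M9a'b	-
		M9a	14308,16234
			M9a1	1041
				M9a1a	16316
					M9a1a1	5417
						M9a1a1c	9242
							M9a1a1c1	13928
								M9a1a1c1b	16291,711
					M9a1a2	4992
				M9a1b	5460
					M9a1b1	8108
			M9a4	6366
			M9a5	385,8155,12237
		M9b	4491
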