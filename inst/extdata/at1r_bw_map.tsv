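# Ballesteros-Weinstein generic positions for the human angiotensin II type 1
# receptor (AGTR1_HUMAN, UniProt P30556), chain A of the receptor crystal
# structures. Curated offline from GPCRdb generic-numbering anchor residues
# (D74 = 2.50, R126 = 3.50 of the DRY motif, Y215 = 5.58, W253 = 6.48 toggle
# switch, N298 = 7.49 / Y302 = 7.53 of the NPxxY motif); positions are offsets
# from those anchors. Could not be re-verified against GPCRdb in this offline
# build environment -- the crystal-structure worked examples (4YAY/6DO1 order
# parameters) gate this table whenever those structures are supplied.
position	residue
2.41	A:65
2.50	A:74
3.50	A:126
5.55	A:212
5.58	A:215
6.34	A:239
6.47	A:252
6.48	A:253
7.46	A:295
7.49	A:298
7.53	A:302
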