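# Domain map of human TRPA1 (1119 aa) for region-sliced rate analysis.
# ILLUSTRATIVE DEFAULTS: exact residue boundaries of the ankyrin-repeat
# stack and transmembrane helices are not sourced from a structure; edit
# to your annotation of choice before real-data use. Quantitative tests
# use simulator-defined maps, never these intervals.
reference: human_TRPA1
reference_length: 1119
region ARD1_9: 1-445
region ARD10_16_linker: 446-719
region S1_S6_COOH: 720-1119
region S5: 864-895
ard ARD1: 61-93
ard ARD2: 97-129
ard ARD3: 133-165
ard ARD4: 169-201
ard ARD5: 205-237
ard ARD6: 241-273
ard ARD7: 277-309
ard ARD8: 313-345
ard ARD9: 349-381
ard ARD10: 385-417
ard ARD11: 421-453
ard ARD12: 457-489
ard ARD13: 493-525
ard ARD14: 529-561
ard ARD15: 565-597
ard ARD16: 601-633
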