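# Target-site definitions: blocks of key = value lines separated by a
# blank line; read with recseq::read_sites().
#
# Half-site positions are numbered center-out from the innermost base
# (numbering_start, default core_length/2 + 1).

name = loxP
left_half = ATAACTTCGTATA
core = ATGTATGC
right_half = TATACGAAGTTAT

# target of the evolved variant Tre (50% diverged from loxP)
name = loxLTR
left_half = ACAACATCCTATT
core = ACACCCTA
right_half = TATGCCAACATGG

# target of the evolved variant Brec1 (68% diverged from loxP)
name = loxBTR
left_half = AACCCACTGCTTA
core = AGCCTCAA
right_half = TAAAGCTTGCCTT

# Placeholders: fill in from your own site definitions before use.
# rox (Dre) and loxV (VCre) follow the Cre-family 13/8/13 layout; the
# Bxb1 attP/attB sites have unequal half-sites and a 2-bp core, so both
# the partition and numbering_start must be supplied explicitly, e.g.:
#
# name = rox
# left_half = <13 nt>
# core = <8 nt>
# right_half = <13 nt>
#
# name = attP
# left_half = <nt>
# core = <2 nt>
# right_half = <nt>
# numbering_start = 1
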