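# Example four-species nonbonded table for an alkane/perfluoroalkane-style
# mixture: hydrogens (H) and carbons (C_H) of the alkane, fluorines (F) and
# carbons (C_F) of the perfluoroalkane. Lennard-Jones epsilon in kcal/mol,
# sigma in Angstrom, charge in elementary charges. Charges here are
# illustrative placeholders, not a validated charge set.
[species]
# label epsilon sigma charge
H    0.030  2.50   0.06
C_H  0.066  3.50  -0.18
F    0.053  2.95  -0.12
C_F  0.066  3.50   0.24

# Uncomment to bypass the combination rule for one pair (values verbatim):
# [pair_overrides]
# H  F  0.025  2.90
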