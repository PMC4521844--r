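# Default anchor set for class / subgroup assignment.
# Human SMYD1-5 anchor the five classes observable in vertebrates; the
# Drosophila melanogaster Smyd4-class genes anchor the Smyd4 subgroups.
# CG1868 sits in the Smyd4 group (closest to human SMYD4); CG14122 and
# CG7759 sit in the Smyd4L group. CG8378 is listed as Smyd4I by inference:
# the four fly genes split one per Smyd4 group, two per Smyd4L and one per
# Smyd4I, and CG8378 pairs with CG1868 by expression, leaving it as the
# Smyd4I member. Override this file if that inference does not suit.
id	class	subgroup
SMYD1_HUMAN	SMYD3	SMYD1
SMYD2_HUMAN	SMYD3	SMYD2
SMYD3_HUMAN	SMYD3	SMYD3
SMYD4_HUMAN	SMYD4	SMYD4
SMYD5_HUMAN	SMYD5	NA
CG1868	SMYD4	SMYD4
CG14122	SMYD4	SMYD4L
CG7759	SMYD4	SMYD4L
CG8378	SMYD4	SMYD4I
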