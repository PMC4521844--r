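# Synthetic reconstruction of the MYND-type cross-brace Zn-finger signature
# (PROSITE-style). Built from the published description of the motif: four
# ligand pairs, short invariant within-pair spacing (C-x(2)-C), a long and
# variable spacer between pairs 1-2 and 3-4, a short fixed spacer between
# pairs 2-3, cysteine ligands with histidine tolerated at the final position.
# This file is the single source of truth for the unrelaxed pattern bounds.
# element types: ligand (allowed = residue set) or gap (min/max = residues
# between the flanking ligands).
element	type	allowed	min	max
L1	ligand	C	NA	NA
G12	gap	NA	2	2
L2	ligand	C	NA	NA
S12	gap	NA	9	21
L3	ligand	C	NA	NA
G34	gap	NA	2	2
L4	ligand	C	NA	NA
S23	gap	NA	4	4
L5	ligand	C	NA	NA
G56	gap	NA	2	2
L6	ligand	C	NA	NA
S34	gap	NA	8	17
L7	ligand	C	NA	NA
G78	gap	NA	2	2
L8	ligand	CH	NA	NA
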