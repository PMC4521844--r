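---
title: "Classifying Smyd proteins from tree and architecture evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Smyd proteins from tree and architecture evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smydfam)
```

## The problem and the model

Smyd proteins are defined by a conserved core: a SET
(histone-methyltransferase) domain interrupted by a MYND-type zinc finger,
followed by a cysteine-rich post-SET region. Outside that core the family
diverges into characteristic architectures — a C-terminal TPR-fold domain
(CTD) in the Smyd3 class, an additional N-terminal TPR block in Smyd4, a
C-terminal acidic tract instead of a CTD in Smyd5, a bare core in the
arthropod-specific SmydA class, and N-terminal TPRs plus an extra C-terminal
MYND finger in a small atypical group. Because the family has undergone
repeated duplication, loss and lineage-specific expansion, similarity to a
vertebrate gene is not a safe basis for naming orthologs.

`smydfam` therefore combines two independent evidence channels:

1. **Tree evidence.** Pairwise distances over the aligned SET-MYND core,
   neighbor joining, and bootstrap support. A query is tentatively assigned
   the class of the *smallest* clade (induced by an internal edge with
   support at or above a threshold) that contains the query and at least one
   reference anchor, provided every anchor inside that clade carries the
   same label. Because any larger clade containing a mixed-anchor clade is
   itself mixed, the search still scans clades in increasing size and stops
   at the first unanimous one.
2. **Architecture evidence.** Detected core, finger category, acidic tract
   and externally supplied TPR_N/CTD annotations are reduced to a signature
   (`TPR_N|S/ET+M|CTD` and so on), and the signature maps to candidate
   classes. Architecture never overrides the tree: a contradiction demotes
   the call to `UNCLASSIFIED` with a disagreement flag, because domain
   structure is treated as independent confirmation, not primary evidence.
   Only when no supported anchored clade exists does a *unique* architecture
   class stand on its own (`architecture-only` evidence).

## The MYND cross-brace finger

The finger model is eight Zn-ligand residues in four pairs; pairs 1 and 3
bind the first Zn ion, pairs 2 and 4 the second (the cross-brace topology).
Within-pair spacing is short and fixed (C-x(2)-C); the spacers between pairs
1–2 and 3–4 are long and variable, the spacer between pairs 2–3 short. The
bundled signature file (`inst/extdata/mynd_zf_pattern_synthetic.tsv`) is a
synthetic reconstruction of the public MYND signature assembled from the
motif's published description; it is the single source of truth for the
unrelaxed bounds, and users can substitute their own file.

The search enumerates all ligand octets satisfying *relaxed* bounds and
reports each hit's deviations from the *unrelaxed* signature:
`spacing_long`, `spacing_short`, `ligand_substitution`, `missing_pair`. The
relaxation policy defaults were chosen to make the extreme known fingers
findable while keeping the search bounded: spacers may overshoot by up to
100 residues (plant relatives of the family carry spacers of more than 80
residues), undershoot by up to 3, within-pair gaps get one residue of slack,
His↔Cys swaps are allowed, and Glu ligands only behind an explicit flag
(exactly one such case is known). The score is the unweighted deviation
count — the literature ranks deviations only qualitatively, so weighting
would imply precision we do not have.

Categories are a pure function of the deviation list: `canonical` (empty),
`partial_left`/`partial_right` (exactly one of the two halves — pairs 1–2
with their spacer and ligands, or pairs 3–4 with theirs — deviation-free;
the central 2–3 spacer belongs to neither half, so a hit deviating only
there is `atypical`), `half` for four-ligand hits interpretable as pairs 1
and 3 (able to bind a single Zn ion), `atypical` otherwise. Half fingers are
only searched when no full finger exists, so they never shadow a full hit.

## Distances, neighbor joining and bootstrap

Four distance kinds are supported. The closed forms are `p` (fraction of
differing usable sites; `X` counts as a mismatch even against `X`, since an
unknown residue can never be evidence of identity), `poisson`
(−ln(1−p)) and `poisson_gamma`, *d* = *a*[(1−p)^(−1/*a*) − 1] with gamma
shape *a* = 5 by default — the standard gamma-corrected protein distance.
`jtt_ml` / `jtt_ml_gamma` are one-parameter maximum-likelihood times under
the empirical JTT exchangeability matrix (computed via phangorn's
`dist.ml`, with a 5-category discrete gamma in the gamma variant); the
closed-form `poisson_gamma` doubles as a fast cross-check for them.
Saturated pairs (p ≥ 1 is impossible, but p = 1 exactly) raise an error
rather than returning infinity, and pairs with zero usable sites are an
error naming the pair.

Column policies mirror standard practice: partial deletion keeps columns
with non-gap fraction ≥ 0.65 by default (ties at the cutoff are kept, and
coverage is computed over all rows including the reference — the upstream
tools do not document their convention, so ours is explicit and
configurable); complete deletion keeps gap-free columns; pairwise deletion
defers to per-pair shared sites.

Neighbor joining is the textbook Q-criterion agglomeration with two
determinism guarantees that matter for reproducible bootstraps: ties in Q
are broken by the lexicographically smallest pair of cluster labels (each
cluster labelled by its smallest leaf name), and negative branch lengths are
clamped to zero with the deficit moved to the sibling edge (raw values kept
in an attribute). Bootstrap support resamples columns with replacement under
a caller-supplied seed, rebuilds the tree per replicate, and annotates each
internal edge of the point-estimate tree with the percentage of replicates
containing the same bipartition — support is mapped onto the point tree, not
a consensus, which is how bootstrap percentages are conventionally displayed
on a published tree. Trees without support annotations are treated as fully
supported during classification, so the pipeline works with or without a
bootstrap stage.

## Homology filter

The filter reproduces three acceptance rules on externally produced BLASTP
tabular files: best hit E-value strictly below 10⁻⁷; continuity — a single
HSP covering at least 90 % of the reference core (residues 18–279 of the
reference by default) — and reciprocal best hit membership in the seed set.
Two operationalizations deserve note. First, HSPs are never merged to
satisfy continuity; if two HSPs each cover half the core the candidate
fails. Second, 12-column tabular rows do not expose individual gap sizes,
so "no large unaligned internal break" is measured as the net indel
imbalance |(qend−qstart) − (send−sstart)| of the covering HSP, capped at 10
residues by default. Best-hit ordering is fully deterministic (E-value,
then bitscore, then subject id), so verdicts are independent of row order.

## Architecture detection

The acidic-tract detector returns the longest C-terminal-anchored suffix
whose combined E+D+S fraction is at least 0.6 with length at least 10. No
published threshold exists for what counts as a "tract"; these values accept
poly-E tails and E/D or E/D/S mixtures while rejecting typical C termini,
and both are exposed as arguments. A consequence of the longest-suffix
definition is that a pure poly-E tail can extend a few residues into the
preceding sequence and be classed `ED` or `EDS` rather than `E`; class
assignment depends only on tract presence, so this affects reporting, not
classification.

The TPR heuristic scores 34-residue windows against a bundled synthetic
position-weight profile built around the classic TPR consensus positions
(W4, L7, G8, Y11, A20, F24, A27, P32). The default threshold of 12 was
frozen after measuring the null distribution on ligand-free random
sequences (maximum observed window score about 11 over hundreds of trials;
a consensus repeat scores 15). It exists so the synthetic pipeline runs
with no external tools; external annotations always take precedence, and
the CTD — a TPR-fold domain not reliably detectable from sequence by a
profile this crude — is accepted *only* from external annotations or the
generator's truth. Its absence is therefore never evidence against
Smyd3/Smyd4 when no external annotations were provided.

## The synthetic generator

The generator emulates a Smyd-like family at the scale of the real study: a
handful of members per class (defaults: 4 Smyd3, 6 Smyd4 split 2/2/2 across
the Smyd4/Smyd4L/Smyd4I groups, 4 Smyd5, 4 SmydA, 2 atypical), one
family-root template evolved along class Yule subtrees hanging off a fixed
pectinate backbone, independent-site substitution (uniform 20-state by
default, JTT optionally), and class surgery that plants the diagnostic
features: per-class finger realizations (canonical in Smyd3/Smyd4, over-long
1–2 spacer in Smyd5 and the atypical class, two His-for-Cys swaps in SmydA),
TPR_N/CTD blocks, an extra C-terminal canonical finger for the atypical
class, and an acidic tail for Smyd5. Absent blocks become gap columns, so
the emitted alignment *is* the true alignment; no indel process is
simulated. Planted feature columns are masked invariant by default.

Filler residues deliberately exclude C, H and E so planted fingers are the
only ligand octets in a generated sequence — detector stress tests use
separate richer compositions. Branch lengths are floored at 0.02
substitutions per site after scaling: a benchmark tree with a near-zero
internal edge is unidentifiable at any finite sequence length, so the floor
is what makes "exact topology recovery" a well-posed requirement
(0.02 × 2000 sites ≈ 40 expected substitutions on the shortest branch).
Divergence is parameterized as expected root-to-tip substitutions per site
within a class (default 0.3) and controls branch scale monotonically.

What passing synthetic tests does **not** show about real data: no indels
(real Clustal alignments are gappier, which is why the column policies
exist), no rate heterogeneity across sites beyond the mask, no alignment
error (the true alignment is emitted directly; the aligner is out of scope
and pluggable), and filler composition is uniform rather than realistic.

## Numerical choices and degenerate inputs

* NJ tie-breaks and negative-branch clamping as above; exact-equality ties
  are detected with a 10⁻¹² slack on the Q minimum.
* Distance matrices with a zero-usable-site pair, saturated Poisson pairs,
  alignments with all-gap rows, empty FASTA files, trees with fewer than
  three taxa, masks longer than the root sequence, and anchors missing from
  the tree all raise immediate, named errors rather than propagating NaN.
* The classification threshold `min_support = 70` is a conventional
  bootstrap cutoff; published analyses of this family use support only
  qualitatively. Raising it is monotonically conservative (it can only move
  calls toward `UNCLASSIFIED`), which the tests verify.
* The bundled anchor table places the reference Drosophila Smyd4-class
  genes in their groups; the Smyd4I membership of one gene is an inference
  from group counts and expression pairing, flagged in the file's comments
  and overridable.

## Problem sizes used in validation

The shipped tests and the acceptance script use 200 random additive
matrices of 4–12 taxa (with a brute-force least-squares oracle over all
topologies up to 6 taxa), 100 random sequences for the finger-search oracle
(9–13 candidate ligands each, so exhaustive octet enumeration stays in the
thousands of combinations), 20-taxon families with 2,000-site cores over 20
seeds for end-to-end recovery, and a 500-replicate bootstrap on a 60 × 260
alignment. These sizes were chosen to exercise every code path at the scale
of the real analysis while keeping a full validation run in the minutes
range on one core.

## Known limitations

* The pipeline consumes alignments; it does not build them. Alignment
  quality is the caller's responsibility.
* JTT maximum-likelihood distances follow phangorn's estimator; numerical
  agreement with other programs' "JTT + gamma" options is not guaranteed,
  since those estimators differ in detail across tools.
* The finger search is exponential in the worst case (many ligand residues
  under generous relaxation); on cysteine-rich regions outside the
  statistical regime it was designed for, restrict the search region or
  tighten the relaxation policy.
* Maximum-likelihood *tree* inference, PFAM/HMM scanning and secondary
  structure prediction are out of scope; their outputs enter as external
  annotation files where relevant.
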