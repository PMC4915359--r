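---
title: "rabscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rabscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`rabscan` re-implements, as a tested and reusable pipeline, the analysis
used to detect and characterise Rab-like small GTPases in proteomes:
profile-based family models, a three-stage classifier with RabF motif
scanning, plurality-rule consensus and per-column entropy comparisons,
C-terminal prenylation-site features, and least-squares superposition of
C-alpha coordinates.  Because the original study's inputs (hundreds of
proteomes, trained classifier models, PDB entries) are external resources,
the package ships a synthetic sequence-family generator with planted ground
truth; every stage is exercised end-to-end on data whose correct answer is
known by construction.

## The profile model

A family is modelled position-specifically from a multiple sequence
alignment.  Columns whose gap fraction is strictly below
`match_gap_threshold` (default 0.5, the usual profile-HMM heuristic) become
match columns.  Emission probabilities per match column are

    e_j(x) = (n_j(x) + c * q(x)) / (N_j + c)

with residue counts `n_j`, ungapped column depth `N_j`, pseudocount weight
`c` (default 1) and background `q` (default uniform 1/20; estimation from
the data is available).  A sequence is scored against the model by a
global affine-gap dynamic programme in which pairing residue `x` with
column `j` contributes `log2(e_j(x)/q(x))` bits, insertions emit against
the background (0 net bits), and gaps pay `gap_open + L * gap_extend` bits
(defaults 4 and 0.25).  This is a profile-HMM Viterbi equivalent without
insert-state emissions — the minimal model supporting every downstream use
(detection, family margins, motif anchoring).  Nonstandard letters (B, Z,
X, U) score 0 bits at any column, i.e. they are background-neutral rather
than errors, which is the lenient behaviour a proteome scan needs.

Two definitional choices deserve a note:

* **Pseudocounts vs row duplication.**  With an absolute pseudocount the
  emission arithmetic above is *not* exactly invariant under duplicating
  every alignment row (the pseudocount's relative weight shrinks).  Match
  columns, consensus, and entropies are invariant, and emissions are
  exactly invariant at `c = 0`; the tests assert precisely that.  We kept
  the count-based formula because it is the standard construction and the
  documented worked example (`"AACC"`, `c = 1` giving 0.41) follows from it.
* **Entropy and gaps.**  Column entropy `H = -sum p log2 p` is computed
  over residue frequencies with gaps excluded (gaps are missing data, not a
  21st symbol; an option exists to include them).  Logo information content
  is `R = log2 20 - H` without small-sample correction; letter heights are
  `p * R`.

The plurality-rule consensus takes the per-column emission argmax
(alphabetical on ties) and writes it upper-case exactly when its
probability exceeds 0.5.

## Pairwise alignment

Global and local alignment use the three-state Gotoh formulation with
affine gaps; the first gapped position costs `gap_open + gap_extend`.
Defaults mirror the EMBOSS `needle`/`water` convention — BLOSUM62 (taken
from Biostrings), open 10, extend 0.5 — because those are the programs the
family-level comparisons emulate; everything is configurable.  Traceback
ties are broken deterministically: diagonal, then gap in the second
sequence, then gap in the first.  Percent identity defaults to the
aligned-columns denominator (gap columns included); a shorter-sequence
denominator is available since conventions differ between tools.  Percent
similarity counts columns whose residue pair scores positive in the
substitution matrix; gap columns are never similar, so similarity is always
at least identity.  The implementation is verified against exhaustive
enumeration of all alignments on small random pairs and against
`Biostrings::pairwiseAlignment` on longer ones.

## The three-stage classifier

1. **G-domain detection.**  A sequence passes when its log-odds score
   against the pooled superfamily profile is at least `stage1_min_bits`
   (default 0 — better than background) and at least `stage1_min_coverage`
   (default 0.5) of the match columns align to residues.
2. **Family assignment.**  The best-scoring family profile wins only when
   its margin over the runner-up reaches `stage2_margin_bits` (default 5
   bits); otherwise the call is `ambiguous`.  Ties break by family name.
3. **Subfamily assignment.**  The stage-3 score of a subfamily is defined
   as its log-odds margin over the generic Rab family model (subfamily bits
   minus family bits).  With the default threshold of 0 this reads "more
   similar to this subfamily than to the family average".  A raw-bits
   threshold of 0 would be vacuous here — any sequence sharing the G-domain
   scaffold scores hundreds of bits against every subfamily profile — and
   would never produce the "Rab-like, no subfamily" outcome that motivates
   the pipeline; the margin form is therefore the package's definition.

RabF motifs are defined on the Rab profile's match columns; each position
carries an allowed set consisting of the consensus residue plus its
BLOSUM62-positive alternatives (capturing conservative pairs such as R/K,
I/L, Y/F).  A motif matches when every one of its columns aligns to a
residue (no gap) inside the allowed set, using the alignment path of the
Rab-profile score.  Motif definitions are data (derived from profiles, or
editable), not code constants.

Final labels: `non-GTPase` (stage 1 fails), the family label or
`ambiguous` (stage 2), `Rab:<subfamily>`, or `Rab-like` when the family is
Rab and no subfamily is sufficiently similar.  An optional motif-rescue
path (`min_rabf_matches`, default 3) can promote an ambiguous family call
with enough RabF evidence to `Rab-like`; it is off by default because the
original pipeline's behaviour on this point is not documented.

All thresholds ship in the model bundle and are reported in the output; the
defaults were chosen once so that the synthetic study conditions sit well
inside the classifier's working range, not tuned to any particular draw.

## The synthetic generator

Families share a common 175-residue G-domain-like scaffold carrying
superfamily-wide nucleotide-binding boxes (a P-loop-like `GDSGVGKT` among
them) and differ by family-specific motif blocks at the five RabF spans
(the Rab family carries the canonical RabF consensus strings IGVDF, KLQIW,
RFRSIT, YYRGA, LVYDIT).  Sequences are independent draws from a star
topology: per-site uniform substitution at `mutation_rate`, protected
blocks untouched.  C-terminal options plant a hypervariable tail (one
ancestral tail per family, mutated per sequence at five times the family
rate so it is poorly conserved at realistic rates yet identical at rate 0)
and a terminal cysteine motif (`CC`, `CXC`, `CCXX`, `XXCC`).  Rab
subfamilies add four protected 3-residue diagnostic blocks outside the RabF
spans and diverge at a lower rate (0.05 vs the 0.10 family default — the
real families' divergence is not documented, so the defaults were chosen to
straddle the classifier's working range).

Ground-truth guarantees worth knowing:

* With `cterm_cys_motif = "none"` the last four residues are kept
  cysteine-free (substitutions there are redrawn from the 18 non-cysteine
  alternatives), so the planted C-terminal class is exactly recomputable
  from the sequence.
* The ablation helper replaces motif positions with residues drawn
  *outside* the allowed set, so a single-motif ablation breaks exactly that
  motif deterministically.
* One master seed drives everything; per-family streams derive from the
  seed plus a stable hash of the family name, so adding a family never
  perturbs another family's sequences.

What the generator does **not** emulate: phylogenetic correlation between
sequences (star topology only), indels inside the domain (gap handling is
exercised through tails, pooled alignments and negatives instead),
compositional bias, and real archaeal divergence levels.  Green tests
therefore certify the machinery — scoring, margins, motif logic, feature
extraction — on data satisfying the model's own assumptions, not the
pipeline's sensitivity on real proteomes.

Because the generator produces no indels, training alignments are built by
right-padding sequences with trailing gaps; tail columns then exceed the
gap-fraction threshold across pooled families and drop out of the match
states, exactly as a hypervariable region should.  Real applications would
supply MAFFT-style alignments instead; alignment construction is
deliberately out of scope.

## C-terminal features and conservation analyses

The terminal window is classified against the standard Rab prenylation
motif classes with the fixed priority `CC` > `CXC` > `CCXX` > `XXCC` >
`other-terminal-Cys` (any cysteine within the last three residues).  Note
that a terminal `CC` always matches class `CC` first, so the `XXCC`
generator option is classified as `CC` — the priority order makes the two
indistinguishable from sequence alone.  A polybasic region is flagged at
three or more K/R within the last ten residues; no numeric criterion is
documented for the original analysis, so the count is reported alongside
the flag.

Cross-family motif conservation compares consensus letters at RabF
positions through a joint alignment of the consensus sequences.  When no
curated joint alignment is supplied, a progressive star alignment around
the Rab consensus is computed from the pairwise module — exact for
indel-free synthetic families, but it does not realign insertions between
non-reference pairs, which is the documented caveat.  Identity is an exact
letter match; similarity is a positive BLOSUM62 score.  Probability-
weighted comparison (rather than consensus letters) would be a reasonable
alternative; consensus letters are implemented because that is what the
logo-level comparison uses.

## Superposition

`kabsch_superpose` computes the least-squares rigid superposition via SVD
with reflection correction, so the rotation is always proper
(`det(R) = +1`) even for mirror-image inputs; no outlier trimming is
applied.  Correspondence defaults to positional pairing of equal-length
sets; an explicit pair list can be supplied.  PDB parsing (bio3d underneath)
keeps C-alpha atoms of one chain and one model, blank-or-`A` alternate
locations, insertion codes in file order.  The synthetic demo pair applies
a random rigid motion plus isotropic 0.25-Angstrom coordinate noise to a
3.8-Angstrom-step C-alpha walk, giving refitted RMSDs around 0.4 Angstrom —
the sub-Angstrom regime of crystallographically similar G domains.

## Coordinates, determinism, and problem sizes

All user-facing coordinates are 1-based inclusive (the R and Bioconductor
convention).  Every random choice flows from one master seed through named
streams, and `run_pipeline()` writes a manifest with an md5 checksum per
report file; identical configuration and seed reproduce every output
byte-for-byte.

The shipped study conditions are 5 families x 50 test sequences at
substitution rate 0.10 plus 100 negatives, training profiles from 30
sequences per family (10 per family pooled into the superfamily profile),
3 subfamilies at rate 0.05, and 80-residue coordinate sets; the test suite
uses smaller draws of the same conditions for the per-module checks.  These
sizes keep a full run in seconds while leaving the classifier's margins
(hundreds of bits between families) far from the thresholds, so results are
insensitive to the exact sizes.

## Known limitations

* The classifier is a position-specific log-odds scorer, not a full
  profile HMM: no insert-state emissions, no local/glocal modes, no
  E-value calibration.
* Star-merged joint alignments are approximate for families with real
  indel structure.
* The generator's uniform substitution model has no rate heterogeneity
  across sites beyond the protected/hypervariable distinction.
* Family-level percentages (consensus similarity matrices) depend on the
  synthetic conditions and are not comparable to values computed on real
  proteome-scale data.
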