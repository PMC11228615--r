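---
title: "Methods: fingerprint-based stereochemical prediction for PKS ketoreductases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint-based stereochemical prediction for PKS ketoreductases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krstereo)
```

## The model

Ketoreductase (KR) domains of modular *cis*-AT polyketide synthases set
two stereocenters: the β-hydroxy configuration (ʟ for A-type KRs, ᴅ for
B-type; C-type KRs do not reduce at all) and, when the extender unit is
α-substituted, the α-configuration (subtype 1 retains α-ᴅ, subtype 2
epimerizes to α-ʟ). The premise of fingerprint prediction is that these
outcomes correlate with a small number of conserved residues in the
catalytic subdomain (KR_C): LDD for B, W for A, H for A2, P for B2,
plus companion motifs (R/Q on the αDE helix; T/L at position 5; D on the
αE–βE loop; the GM pre-lid pair, whose *absence* marks A2; RLXR vs XLXR
on the lid helix; a lid-terminal H for B2) and the machinery of
reduction itself (catalytic Y and K, the glycine-rich NADPH-binding
site), whose loss marks C-types.

The predictive power of these motifs is stratified. They were derived
from, and hold best for, KRs in β-modules (KS-AT-KR-ACP) of
actinobacterial PKSs. Outside that stratum the package deliberately
claims less: for non-actinobacterial KRs only the LDD/W calls are made
and the α-subtype is reported as unpredictable; for DH-associated
(γ/δ-module) KRs only the presence of the second D of the LDD motif
supports a (tentative) B call, and phylogenetic placement of KR_C is
recommended instead.

## Module typing

Modules are typed purely by domain composition in canonical N→C order —
KS-AT-ACP (α), +KR (β), +DH+KR (γ), +DH+ER+KR (δ) — regardless of
whether the DH or ER is active; an inactive DH (a "DH⁰" module) still
makes the module γ/δ, which matters because DH-associated KR sequences
differ systematically from β-module KRs. Auxiliary domains
(methyltransferases, oxidases) are ignored for typing but reported,
since real clusters carry them; any other arrangement — duplicated KRs,
missing KS, ER without DH, out-of-order domains — is `unconventional`
and is excluded by the curation filters.

## Anchored alignment instead of a full MSA

All motif positions are defined as columns of a packaged 380-column
reference coordinate system (columns 1–150 KR_S, 151–380 KR_C). A query
is globally aligned (Needleman–Wunsch, affine gaps) against each
reference row; the best-scoring row projects the query into column
space. This replaces a full-dataset multiple alignment for prediction:
it requires no external aligner, is deterministic, and keeps column
semantics fixed no matter how many queries are processed. An externally
computed MSA can still be supplied for logo and tree work by passing its
rows directly to `kr_logo`/`kr_distance_matrix`.

Defaults are the community's: BLOSUM62, gap open 11, gap extend 1 (a gap
of length L costs 11 + L). A query covering less than 50% of the
reference columns is rejected as unalignable — in practice this catches
non-KR inputs, since even a KR_C-only query covers ~61% of the columns.
Coordinates are 1-based inclusive in all human-readable output.

The packaged reference profile is **synthetic**: eight ungapped rows on
a common randomized scaffold whose anchor columns carry each
stereotype's literal motifs, with ~4% background divergence between
rows. It is a stand-in for a curated set of published KR sequences and
is labelled synthetic in its file name and headers. The loader
validates, at every load, that the motif-2 columns read `LDD` in a
B-type row and motif 7 reads `W` in an A-type row; users with curated
references can swap them in via `kr_reference_profile(fasta, anchors)`
without touching any other code path.

## The motif catalog and rule engine

The catalog maps 13 numbered anchors plus a four-column NADPH site to
per-stereotype patterns (`X` matches any non-gap residue; gaps never
match). Motif 1 is carried as an inert placeholder — the numbering
convention starts there, but no diagnostic residue is assigned to it.
Motif 2 is graded (`full` LDD / `second_d` / `l_only` / `absent`)
because the γ/δ rule keys on the second D specifically and the A2 rule
on the leading L. GM absence at motif 11 is called only when *neither*
column carries its conserved letter. The NADPH set is a
Rossmann-consensus reconstruction (four glycine positions); the site
counts as intact when ≥ 75% of its positions match.

Decision order in `kr_predict`:

1. **Reduction competence first.** No catalytic Y and no Q surrogate, or
   a non-intact NADPH site, means C-type: β-stereo votes are meaningless
   without reduction. Q at motif 9 is accepted as catalytically
   meaningful only in this C2 context. Within actinobacterial β-modules
   a C-type with subtype-2 markers *and* the conserved K(4) is C2,
   otherwise C1. Two concordant C signals give high confidence, one
   gives moderate.
2. **Actinobacterial β-modules.** A uniform-weight vote: B gets {full
   LDD, R(3), T(5), RLXR(12)}, A gets {W(7), L(5), D(6), XLXR(12) with a
   non-R first residue}. Margin ≥ 2 → high confidence, 1 → moderate,
   tie → ambiguous. The weights are uniform because the motif–type
   correlations are reported individually, with no combination formula;
   a uniform monotone vote is the simplest scheme consistent with using
   "multiple strong predictive motifs", and it makes the monotonicity
   property (an added concordant vote never flips the call or lowers
   confidence) provable. Subtype is resolved only when the substrate is
   α-substituted: A2 on H(8) or (L-only LDD + missing GM), B2 on P(10)
   or terminal H(13), else subtype 1. The α-substitution flag comes from
   the annotations (it is a property of the extender unit, not of the KR
   sequence); when missing it defaults to TRUE with a warning.
3. **Non-actinobacteria.** Full LDD → B (high); else W → A (moderate);
   else ambiguous; subtype is always `unpredictable` because H and P are
   not conserved outside actinobacteria.
4. **Actinobacterial γ/δ.** Second D of LDD → B, at low confidence (or
   moderate when T(5) concurs); anything else is ambiguous. The
   applicability note recommends phylogenetic placement.

Combined labels join letter and digit (`B1`), use `0` for
α-unsubstituted products (`A0`) and drop the digit when the subtype is
out of scope (`B`).

## Phylogenetic fallback

Distances are p-distances over anchored columns with *pairwise* deletion
(complete deletion can empty the comparable set when diverse KRs gap
heavily; the choice is exposed), corrected with the 20-letter
Jukes–Cantor transform d = −(19/20)·ln(1 − (20/19)·p). Saturated pairs
(p ≥ 19/20) raise an error unless the caller supplies a cap. Trees are
standard Saitou–Nei Neighbor-Joining (via `ape::nj`); on additive inputs
the generating topology and branch lengths are recovered exactly, which
the tests verify by construction. Negative NJ branch lengths are clamped
to zero and flagged.

Clade assignment is defined on splits, not rootings: every edge's
query-containing side is an enclosing clade, and the call is the
majority label of the smallest such clade holding ≥ 3 labelled
references at ≥ 0.8 purity. If the smallest qualifying size holds two
clades with conflicting labels the query is `unresolved` — this is what
happens when a query attaches on the edge between two pure clades. The
purity and reference-count thresholds are our operationalization of
"falling within" a clade; they are arguments, not constants.

## Sequence logos

Column frequencies are normalized over non-gap residues; the gap
fraction is reported separately and `1 − gap fraction` is carried as a
width weight, matching the convention that a logo column's width shows
how many sequences contribute a residue there. Information content is
R = log₂20 − H, clamped at zero, with the small-sample correction
e\_n = 19/(2·ln2·n) off by default (group sizes in realistic use make it
negligible; the flag exists for small groups). Frequencies and
information are invariant to row order and to duplicating the whole row
set, which the tests assert.

## The synthetic generator and what it shows

`kr_synth` builds KR_C (or full-length) sequences on the primary
reference scaffold: anchor columns get the stereotype's expected
residues (pattern `X` positions drawn uniformly, with the A-type XLXR
first position drawn from non-R so the pattern semantics stay exact),
non-anchor positions mutate independently at rate 1 − background
identity (default 0.9, a realistic within-clade divergence that still
leaves alignment recovery trivially correct), and each anchor is
corrupted wholesale with probability `anchor_noise` (replacement uniform
over the 19 non-original letters — the simplest null model). Background
mutations never touch anchor columns, so at zero noise label semantics
are exact by construction.

The benchmark suite (9 labels × 25 replicates by default; within each
block of five, two actinobacterial β records, one myxobacterial β, one
cyanobacterial β, one actinobacterial γ/δ with inactive DH) is sized so
the full prediction run takes seconds, and the test and acceptance runs
use it at noise 0 and 0.3 plus 120 brute-force alignment pairs and 50
random additive matrices — sizes chosen to exercise every code path
while keeping the default check quick.

What passing these tests shows: the engine implements its stated rules
exactly, recovers planted labels perfectly when the motifs are intact,
and degrades gracefully and monotonically as motifs are destroyed. What
it does **not** show: performance on real KRs. The generator has no
phylogenetic covariance among background positions, no indels, no
taxon-specific composition, and its anchors are either exactly right or
uniformly random — real sequences violate all four. Claims about real
accuracy must come from a curated, experimentally labelled dataset run
through `kr_predict_batch`, which reports per-label satisfaction rates
and a confusion table for exactly that purpose.

## Degenerate inputs and numerical conventions

Empty sequences, empty domain lists, alpha-modules (no KR), unalignable
queries, all-gap anchors, saturated distances, matrices under 3 taxa and
trees without labelled references all raise typed errors or flagged
warnings rather than propagating nonsense. KR_C-only inputs to the
subdomain splitter return an empty KR_S with a warning (detected as
> 90% gapped KR_S columns). Duplicate-product curation keeps the first
record in input order — a determinism convention, since no retention
rule is derivable from the data itself.

## Known limitations

* The packaged references are synthetic; `clade_assign` against them
  tests machinery, not biology. Real use should supply curated labelled
  references.
* *trans*-AT PKS KRs are out of scope; their motif grammar differs.
* The α-subtype is never predicted outside actinobacterial β-modules,
  and γ/δ predictions are tentative by design.
* The exact membership of the NADPH-binding residue set is a
  reconstruction; users can re-anchor it in the anchors TSV.
* Vote weights are uniform and uncalibrated; the margins are exposed,
  and probabilistic calibration is deliberately not attempted.
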