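# krstereo

Stereochemical prediction for ketoreductase (KR) domains of modular
*cis*-AT polyketide synthases (PKSs), from sequence alone.

## The problem

Modular PKSs assemble polyketides one extender unit at a time; the KR
domain of each module sets the configuration of the β-hydroxy group it
produces and, for α-substituted extender units, can also epimerize the
α-carbon. KRs are classified by outcome:

* **A-type** — ʟ-configured β-hydroxy product;
* **B-type** — ᴅ-configured β-hydroxy product;
* **C-type** — reduction-incompetent (β-keto retained);
* subtype **1** (non-epimerizing, α-ᴅ) vs **2** (epimerizing, α-ʟ) when
  the substrate carries an α-substituent (a trailing **0** marks
  α-unsubstituted products, e.g. `A0`).

Because the product stereochemistry of an uncharacterized biosynthetic
gene cluster is expensive to determine experimentally, conserved sequence
motifs in the catalytic KR subdomain (KR_C) are widely used to predict
it: the classical **LDD** motif marks B-type and **W** marks A-type KRs,
with **H** (A2) and **P** (B2) marking the epimerizing subtypes. These
fingerprints are most reliable for KRs in β-modules (KS-AT-KR-ACP) of
actinobacterial PKSs and degrade for other taxa and for DH-associated
(γ/δ-module) KRs, where companion motifs — R/Q on the αDE helix, T/L at
position 5, D on the αE–βE loop, the GM pre-lid pair, the RLXR/XLXR lid
motif, the lid-terminal H, the catalytic Y/K pair and the glycine-rich
NADPH-binding site — sharpen or bound what can be predicted.

`krstereo` implements this fingerprint method end to end:

* **module typing** — α/β/γ/δ classification from domain composition,
  independent of domain activity (`classify_module`);
* **anchored alignment** — global affine-gap alignment of any query onto
  a packaged reference coordinate system, so every motif is addressable
  by column (`anchor_map`, `split_subdomains`);
* **motif calls** — per-anchor observation and stereotype tagging
  (`kr_catalog`, `call_motifs`, `nadph_site_intact`);
* **stratified rule engine** — a vote between A- and B-motifs for
  actinobacterial β-modules, LDD/W-only calls for other taxa, a
  second-D-of-LDD call for γ/δ-modules, and a reduction-competence branch
  that intercepts C-types (`kr_predict`, `kr_predict_batch`);
* **phylogenetic fallback** — Jukes–Cantor-corrected distances
  (d = −(19/20)·ln(1 − (20/19)·p)), Neighbor-Joining trees and
  clade-membership assignment (`kr_distance_matrix`, `kr_nj_tree`,
  `clade_assign`);
* **sequence logos** — per-column frequencies and information content in
  bits for motif re-derivation on labelled datasets (`kr_logo`,
  `group_logos`);
* **dataset curation and statistics** (`read_kr_dataset`, `curate_kr`,
  `kr_dataset_stats`) and a **synthetic benchmark generator**
  (`kr_synth`, `kr_benchmark_suite`).

The packaged reference alignment is a *synthetic* seed set (its anchor
columns carry the literal motifs; see
`inst/extdata/kr_reference_synthetic.fasta`); you can substitute your own
curated references via `kr_reference_profile(fasta, anchors)`.

## Worked example

```r
library(krstereo)

queries <- kr_dataset(rbind(as.data.frame(kr_synth("B1", 2, seed = 101)),
                            as.data.frame(kr_synth("A2", 1, seed = 102))))
pred <- kr_predict_batch(queries)
print(pred)
#> KR predictions: 3 records (3 aligned)
#>               id module_type    taxon_group combined_label confidence
#>  syn_B1_acti_001        beta actinobacteria             B1       high
#>  syn_B1_acti_002        beta actinobacteria             B1       high
#>  syn_A2_acti_001        beta actinobacteria             A2       high
#> per-label recovery of ground truth:
#> A2 B1
#>  1  1
```

Each combined label joins the β-stereochemistry letter with the
α-subtype digit; `confidence` reflects the vote margin among concordant
motifs. Per-record evidence is available from the single-query path:

```r
anc <- anchor_map(queries[3, , drop = FALSE], kr_reference_profile())
kr_predict(call_motifs(anc), "actinobacteria", "beta", TRUE)
#> KR prediction for 'syn_A2_acti_001': A2 (beta-stereo A, subtype 2), confidence high
#>   evidence:
#>     motif7     W      W -> A
#>     motif5     L      L -> A
#>     motif6     D      D -> A
#>     motif12    MLCR   XLXR (non-R first) -> A
#>     motif8     H      A2 markers -> subtype 2
```

The `W`, `L`, `D` and `XLXR` observations are the A-type fingerprint; the
`H` at motif 8 upgrades the call to the epimerizing subtype A2.

A command-line interface wraps the same functions:

```sh
exec/krstereo predict --fasta queries.fasta --annotations ann.tsv --out pred.tsv
exec/krstereo classify-module --domains KS,AT,DH,KR,ACP   # gamma
```

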