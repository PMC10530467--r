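---
title: "famvarnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famvarnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Families with several members affected by venous thromboembolism (VTE) but
no recognized thrombophilic defect are a classical setting for whole-exome
sequencing: the hypothesis is that combinations of low-frequency missense
variants in hemostasis- and VTE-related candidate genes, each of small
effect, jointly shape susceptibility. famvarnet implements the downstream
analysis of such a study as a reusable, tested pipeline:

1. **Filter** multi-sample genotypes to low-frequency, high-quality
   variants in a candidate panel that segregate with disease;
2. **Summarize segregation**: carrier matrices, per-patient burden,
   variants shared by every affected member, linkage/compound-heterozygous
   groups;
3. **Prioritize** missense variants by a consensus of 15 deleteriousness
   predictors joined with eQTL/sQTL and ClinVar evidence;
4. **Infer per-patient protein-interaction networks** from channelized
   evidence scores, and test functional term enrichment.

Upstream steps (read mapping, variant calling, running VEP/GTEx/SpliceAI or
the 15 predictors themselves) are out of scope; their outputs are consumed
as annotation tables.

## Filtering and segregation model

A variant is retained when all of the following hold:

* its gene is on the candidate panel (symbols uppercase-normalized);
* call quality `Q > qual_min` (default 30, strict);
* minor allele frequency `MAF < maf_max` (default 0.04, strict) in **both**
  population databases (gnomAD3 and 1000G). A variant absent from a
  database passes that database's test: unreported variants are by
  construction rare, and the workflow deliberately retains novel variants
  with no frequency entry at all;
* at least one **affected** member is **heterozygous** for it. A
  homozygous-alternate genotype alone does not satisfy this requirement
  (the filter is defined on heterozygosity), but hom-alt members still
  count as carriers in every downstream summary.

Carriers are members with a `het` or `hom_alt` genotype. The
shared-in-affected set is the intersection of carrier sets over all
affected members. Linkage groups are maximal same-gene variant sets
co-carried by a member; without phase information true linkage cannot be
distinguished from compound heterozygosity, so both are reported as one
group kind. All outputs are sorted by `(chrom, pos, alt)` so that repeated
runs are byte-identical.

## Predictor consensus and ranking

Fifteen tools are arranged as a variants-by-tools score matrix. All scores
are ingested on a common "higher = more damaging" [0, 1] orientation
(tools such as SIFT, whose native scale is inverted, must be mapped at
ingestion; the mapping belongs to the configuration, not the algorithm).
Per tool, two cutoffs define three categories:

```
score >= damaging_min  -> damaging
score <= neutral_max   -> neutral
otherwise              -> moderate      (absent score -> missing)
```

The *damaging votes* of a variant is its number of damaging tools.
Missense variants are ranked by descending REVEL score (an ensemble of 13
component predictors), with ties broken by votes (descending) then gene
symbol; quartiles are assigned by rank position, `ceiling(4 r / n)`, which
matches the "ranking position" language of the workflow rather than score
values. Variants without a REVEL score are placed after all ranked
variants with `NA` rank but remain vote-counted and eligible for
prioritization.

Per-tool cutoffs are not universal constants; the packaged fixture pins
`damaging_min = 0.5`, `neutral_max = 0.25` for all tools, which reproduces
the study's reported vote counts, and both are configuration columns. The
fifteenth tool slot is configurable (`prediction_tools(extra = )`, default
`CADD`): the source workflow names fourteen algorithms explicitly.

## Prioritization rules

Two evidence flags mirror the study's heatmap highlighting:

* `+` : carried by at least `affected_min` (default 2) affected members
  **and** damaging by at least `votes_min` (default 4) tools;
* `*` : damaging by at least `votes_min` tools **and** supported by
  eQTL/sQTL genes or a ClinVar report (`clinvar_star` chooses whether any
  reported category counts, or LP/P only; default any, with reason codes
  making each decision auditable).

The *status* rule is deliberately separate from the flags. The default,
`low_evidence_exclusion`, drops a variant only when it has fewer than
`votes_min` damaging votes **and** no functional correlates (no QTL genes,
no LP/P ClinVar category); everything else is prioritized. This was a
genuinely open design point: a flags-only rule looks cleaner, but it can
never prioritize a variant carried by a single affected member that lacks
QTL and ClinVar entries, however unanimous the predictor consensus — and
the study's own selection demonstrably retained such variants while
excluding only the low-vote, evidence-free tail of the ranking. The
flags-only alternative is kept as `status_rule = "flags_only"`.
Manual includes (frequent, functionally characterized variants added to
the network analysis by design, e.g. a fibrinogen-beta coding variant) are
marked `manual_include` and never counted as rule-prioritized.

## Interaction networks

Per-patient node sets are the genes of network-eligible prioritized
variants the patient carries, plus per-patient extra includes (the
frequent functional variants; one only where homozygous). Network
eligibility is an explicit configuration list because the source
workflow's exclusions of some prioritized genes follow no stated rule.

Edges come from a channelized evidence database (neighborhood, fusion,
cooccurrence, experimental, database, coexpression; textmining is
supported in the data model but absent from the fixture). Channel scores
are combined STRING-style by a prior-corrected noisy-OR with prior
`p = 0.041`:

```
s_i' = (s_i - p) / (1 - p)
u    = 1 - prod_i (1 - s_i')
S    = u (1 - p) + p
```

With one channel this returns that channel's score exactly; with none it
returns `p`; it is symmetric in channel order and monotone in added
channels, and always lies in `[p, 1)`. Channels scoring below the prior
carry no information beyond it and are dropped with a warning. Combined
scores are tiered at lower bounds 0.15 / 0.4 / 0.7 / 0.9 (half-open bins:
a score exactly at a bound belongs to the higher tier; below 0.15 is
`below_low`).

Enrichment is an upper-tail hypergeometric test per term
(`p = P(X >= k)` with `N` background genes, `K` term genes, `n` query
genes, `k` overlaps), adjusted by Benjamini–Hochberg within each term
category (GO-BP, GO-CC, keyword). Whether the source analysis adjusted
within category or globally is not stated; within-category was chosen
because the categories come from different annotation universes. Absolute
enrichment FDRs printed by STRING are database-version dependent and are
*not* reproduced or asserted; the package validates enrichment against
closed-form oracles and qualitative term recovery.

## The packaged fixture

`load_paper_fixture()` returns the study's printed data as standard files:
the six-member, three-generation pedigree (three affected: II2, II3,
III2), the 22 low-frequency records with their carriers, gnomAD3
frequencies and ClinVar categories, the regulatory/QTL table, frequent
supplementary variants (which also exercise the linkage-group logic), and
deliberately failing distractors (MAF at exactly the threshold in one
database, quality below threshold, off-panel gene, het only in unaffected
members, hom-alt only in affected, a multiallelic site).

Three parts of the fixture are synthetic stand-ins, labelled as such:

* **Raw predictor scores.** The printed probability panel is not
  machine-readable; the fixture's scores are synthetic values whose
  *categories* and REVEL ordering are consistent with every reported
  count (vote counts, quartile placements, top-5 ranking). Categories,
  not raw scores, are the ground truth.
* **Genomic coordinates and a few rsids** of supplementary variants are
  plausible inventions (positions are not printed).
* **1000G frequencies** reuse the printed gnomAD3 values (only one
  database's frequencies are printed; the filter result is unaffected).
* **Channel scores** in the mini edge database are synthetic values chosen
  so the combined scores fall in the reported confidence tiers; only
  tier-level claims are asserted.

The two novel variants are modelled with absent MAFs plus a novel flag,
and *do* carry REVEL scores in the fixture: position-based ensemble scores
exist for variants never observed in population databases, and the source
ranking demonstrably included both.

## The synthetic generator

`generate_family()` emulates the statistical structure the analysis
assumes: a three-generation pedigree with configurable affected count; a
panel-restricted variant set whose MAF spectrum mixes a very-rare point
mass (default 30% of variants, MAF 1e-6 to 1e-4) with a uniform tail up to
0.3; planted shared-in-affected variants (het in every affected member)
and planted compound-het gene pairs; predictor scores driven by a latent
"true deleteriousness" with configurable correlation (`rho = 1` makes all
tools agree; `rho = 0` reduces agreement to chance, 0.375 under the
default cutoffs); and beta-distributed per-channel interaction evidence.
The generator guarantees the planted truths are recoverable (planted
variants always pass the filter; no other variant is accidentally carried
by all affected members) and writes a JSON manifest of every planted fact.

What it does **not** emulate — and hence what a green round-trip test does
not establish: Mendelian transmission (non-planted genotypes are sampled
per member from Hardy–Weinberg proportions independently of the pedigree),
linkage disequilibrium, read-level error, and any phenotype model.
Randomness comes from a single `set.seed(config$seed)` at entry (the
R-idiomatic equivalent of passing one generator through all sampling
calls), making every output byte-reproducible.

## Numerical choices and degenerate inputs

* Strict inequalities: `MAF < maf_max`, `Q > qual_min`; a variant at
  exactly 0.04 or quality exactly 30 is excluded.
* Category boundaries are inclusive on both cutoffs
  (`>= damaging_min` damaging, `<= neutral_max` neutral).
* Tier bins are half-open with inclusive lower bounds.
* Empty inputs: an empty VCF yields an empty variant set; an empty
  decision table exports header-only heatmaps; a node set without
  database pairs yields an edgeless network; enrichment of a term
  covering the whole background has `p = 1`.
* Unparsable genotypes become `missing` with a warning (record-level,
  never fatal); missing samples, duplicate pedigree ids, conflicting
  annotation duplicates and out-of-range scores are fatal.

## Known limitations

* No liftover, indel normalization, HWE/LD statistics or imputation.
* "Linkage" vs compound heterozygosity is not resolved (no phase).
* The prioritization reproduces a rule-based reading of a partly manual
  selection; reason codes expose every decision for audit.
* Enrichment backgrounds are declared, not derived from an annotation
  release; absolute FDRs are therefore not comparable to live STRING.
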