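---
title: "Classifying C4-pathway gene copies in grass genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying C4-pathway gene copies in grass genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4ortho)
```

## The problem

C4 photosynthesis in grasses runs on six enzyme families — beta carbonic
anhydrase (beta-CA), the Rubisco small subunit (RbcS), PEP carboxylase
(PEPC), NADP-dependent malic enzyme (NADP-ME), malate dehydrogenase (MDH),
and pyruvate orthophosphate dikinase (PPDK). Every family is present in C3
grasses too; within each family only particular gene copies were recruited
into the C4 pathway. `c4ortho` implements a desk-scale pipeline that, given
standard upstream artifacts (homology-search tables, protein alignments,
gene models, expression matrices, localization annotations), identifies
family members across five crop genomes (maize, sorghum, foxtail millet
as C4; rice, wheat as C3) and labels each copy **C4-type**,
**non-photosynthetic**, or **indeterminate**.

The pipeline combines six lines of evidence per copy:

1. **Orthogroup membership** — a neighbour-joining tree from JTT maximum
   likelihood distances, bootstrap support, and a clade cut; the orthogroup
   containing a known C4 anchor gene (e.g. the maize C4 copy) is the
   family's C4 lineage.
2. **Diagnostic residues** — e.g. the C-terminal serine of C4 PEPC and the
   glycine/alanine contrast near it; asparagine vs isoleucine at the RbcS
   site homologous to OsRbcS1 residue 56; aspartate/glycine at OsMDH1
   residue 43 separating NAD- from NADP-dependent MDH.
3. **Subcellular localization** — predictor annotations first, chloroplast
   transit peptide (cTP) evidence second; NADP-ME and MDH C4 copies must be
   chloroplastic, and PPDK's chloroplast isoform is the transcript that
   retains exon 1.
4. **Tissue specificity** — the EL statistic (below) with a leaf-dominance
   rule.
5. **Tandem duplication structure** — recorded as context (it drives family
   expansion) but not a classification criterion.
6. **Promoter cis-elements** — descriptive comparison of element densities
   (e.g. CAAT-box, consensus `C(C/A)AAT`) between groups, by upstream bin.

## The EL statistic

Raw FPKM is not comparable across species, so tissue specificity uses the
per-gene share of log-scale expression:

$$\mathrm{EL}_t \;=\; 100 \cdot
  \frac{\log_2(\mathrm{FPKM}_t + 1)}{\sum_{t'} \log_2(\mathrm{FPKM}_{t'} + 1)}$$

over the four tissues root, shoot, spike, leaf. Rows sum to 100 for any
expressed gene; an all-zero gene is flagged unexpressed. A copy is
**leaf-dominant** when its leaf EL is strictly maximal, at least `el_min`
(default 40 percentage points), and leaf FPKM is at least `fpkm_min`
(default 1). EL is implemented from its verbal definition — expression in
one tissue as a proportion of that in all tissues, on the log scale — so
the worked example (FPKM 3,1,0,0 giving EL 66.67/33.33/0/0) comes out
exactly.
The 40/1 thresholds are package defaults chosen to separate strongly
leaf-specific profiles (leaf EL above 50 in clean 20-fold inductions) from
broad ones (25 each); both are configurable and no claim is made that they
are the only reasonable cut.

## Distances, trees, orthogroups

Pairwise distances are maximum likelihood estimates of divergence time
under the JTT empirical substitution model: columns with a gap or unknown
residue in either sequence are dropped (pairwise deletion), and the
distance maximises $\sum_{ij} n_{ij}\log(\pi_i P_{ij}(t))$ over $t$, with
$P(t) = e^{Qt}$ from the published JTT generator normalised to one
expected substitution per site per unit time and JTT stationary
frequencies. The 1-D optimisation runs on $t \in (10^{-8}, 5]$; a pair
whose likelihood is still rising at the bracket end is *saturated* and
reported inestimable — the matrix builder substitutes a capped distance
(default 5.0, with a warning) so trees remain constructible. Tests verify
the optimum against a dense grid search whose matrix exponentials come
from an independent scaling-and-squaring Taylor implementation.

Trees are standard neighbour joining (taxa sorted lexicographically first
so ties resolve deterministically; negative branch lengths clamped to
zero). Bootstrap support resamples alignment columns with replacement,
rebuilds the tree per replicate, and reports the percentage of successful
replicates containing each bipartition of the point tree; failed
replicates are skipped and counted. Support is attached to the point tree;
no consensus tree is built.

Orthogroups are cut from the support-labelled tree: every side of every
bipartition with support at least `min_support` (default 50) is a
candidate, a candidate qualifies when each species contributes at most its
copy limit (default 1; hexaploid wheat is naturally given 3 via the named
`max_copies` argument), and qualifying candidates are accepted greedily,
largest first, without overlap. The full leaf set counts as a trivially
certain candidate, so a small family that already satisfies the limits is
one orthogroup. Working on bipartition sides rather than rooted clades
makes the cut independent of the arbitrary rooting of an unrooted NJ tree.
This cut is an explicit, reproducible approximation of what is otherwise
done by inspection.

## Screening

Family membership requires a best BLAST hit (minimum E-value; ties by
identity, then partner id) with E-value strictly below 1e-5 and identity
at least 60%, plus *every* required conserved domain in the HMMER table
(beta-CA PF00484; RbcS PF12338+PF00101; PEPC PF00311; NADP-ME
PF03949+PF00390; MDH PF02866; PPDK PF02896+PF01326+PF00391). Domain
presence ignores the domain E-value by default, since the protocol states
no domain-level threshold; an optional cutoff exists. Manual curation is
modelled as explicit include/exclude override lists.

## Protein features

Molecular weight sums average residue masses plus one water, the
convention of the ExPASy Compute pI/MW tool; pI is the zero of the
Henderson–Hasselbalch net charge under the Bjellqvist pK set (termini pKs
depending on the terminal residue; D, E, C, Y negative and H, K, R
positive side chains), found by bisection on pH 0–14 to a charge
tolerance of 1e-4. Because the real SbCA3 sequence cannot be bundled, the
calculators are checked on a clearly labelled **synthetic stand-in**: a
448-aa sequence constructed (by an independent implementation of the same
conventions) to carry the reported MW of 48986.93 Da and pI of 8.74.
Passing that check demonstrates the conventions are right, not that any
real protein was measured. cTP calls are consumed from an external
predictor's annotation table; a naive N-terminal heuristic (S/T-rich,
acid-poor first 60 residues) exists only for synthetic tests and flags
itself as low confidence.

## Genome context

Tandem arrays use a rank-gap rule: same-family genes on one chromosome
with at most `max_intervening` (default 5) non-family genes between them
are linked, and arrays are the connected components, singletons excluded.
This deterministically approximates collinearity-tool-plus-curation
duplication calls; an override list is supported. Promoters are the 2000
bp upstream of the initiation codon (strand-aware, truncated with a flag
at chromosome edges). The element scanner matches IUPAC patterns on both
strands, reports overlapping hits with offsets relative to the ATG (−1 is
the base immediately upstream), bins them into −1..−1000 and
−1001..−2000, and never lets an N in the genome match. Built-in element
consensi beyond the CAAT-box (`CMAAT`) are conventional PlantCARE-style
strings and are user-overridable. Group
comparisons report descriptive means only; no hypothesis test is
attached, because none is defined for this contrast.

## Classification rules

Per family, a copy is C4-type only if all required criteria hold:

| family  | required criteria |
|---------|-------------------|
| beta-CA | C4 orthogroup; leaf-dominant |
| RbcS    | leaf-dominant; maximal leaf FPKM in its species |
| PEPC    | C4 orthogroup; C-terminal Ser site in C4 state; leaf-dominant |
| NADP-ME | C4 orthogroup; chloroplast; leaf-dominant |
| MDH     | C4 orthogroup; NADP coenzyme; chloroplast; leaf-dominant |
| PPDK    | chloroplast (exon-1) transcript; leaf-dominant |

Any failing criterion gives non-photosynthetic (with the failures as
reasons); unknown-but-not-failing evidence gives indeterminate. RbcS is
expression-only because its family expanded after speciation, making
cross-species orthogroups unreliable; the within-species maximal-leaf-FPKM
rule picks one representative per species, ties broken by gene id. C3-crop
copies that satisfy every sequence criterion but fail leaf dominance are
deliberately labelled non-photosynthetic with reason `leaf_dominant` —
the C4-orthologous copies in C3 crops are expressed too low to count as
functioning C4 genes. PPDK genes with a dual-promoter model are classified
per transcript: the exon-1-containing transcript is the chloroplast
isoform, the intron-1-initiated one the cytosolic isoform.

## The synthetic scenario

`generate_scenario()` is first-class, tested code that emulates the
study's data shapes with planted truth: 5 species (3 C4), six families
with 2–4 orthogroups each (one copy per species per orthogroup, roughly
10–20 genes per family — the scale of these small families), proteins of
120 aligned columns simulated along a two-level tree (orthogroups diverge
at 0.7 substitutions/site, species copies at 0.08) under the same JTT
model used for estimation, indel-free so the simulated sequences are
already aligned. Planted signals: diagnostic residues (PEPC Ser site,
MDH coenzyme site), 50-aa S/T-rich cTP leaders on chloroplast copies,
tandem pairs/triples versus isolated genes separated by more than five
filler genes, promoters with exact planted element counts per bin (the
background is scrubbed of chance matches first), and negative binomial
counts (dispersion 0.1, library size 2e7) around planted FPKM profiles in
which C4 copies have a 20-fold leaf induction over a low baseline and
every other copy is root-, spike-biased or broad. C3-species members of a
C4 orthogroup get non-leaf-dominant profiles, mirroring the finding that
C4 orthologues in C3 crops are expressed at much lower leaf levels.

What passing means — and does not mean. Exact recovery
(precision = recall = 1 at default effect sizes, collapsing to recall ≈ 0
at 1x leaf fold) shows the machinery is wired correctly and the decision
rules respond to the planted signal, with clean dose-response. Real data
differ in ways the generator deliberately omits: alignments have indels
and alignment error, expression has batch and tissue-composition effects,
orthology is blurred by gene conversion and polyploidy, and localization
predictors err. Results on real genomes therefore inherit the quality of
the upstream artifacts; the tests certify the pipeline, not the biology.

## Numerical choices and degenerate inputs

* JTT optimisation tolerance 1e-8 on $t$; saturation declared when the
  optimum is within 1e-4 of the bracket end and the likelihood is
  non-decreasing there.
* pI bisection: bracket [0, 14], at most 200 iterations, charge tolerance
  1e-4.
* NJ ties: input taxa sorted; candidate orthogroups ordered by size then
  first member id.
* Empty screening input gives an empty result, not an error; an empty
  required-domain set is a configuration error.
* Ambiguity parsing: `(X/Y)` is a state set; a parenthesised single
  residue is an insertion and is dropped (a stated convention — the
  source notation is ambiguous); rows that still disagree with the modal
  column count are rejected by name. Unknown residues expand to all 20
  states so they can never fabricate a perfectly discriminating column.
* A missing expression matrix degrades the pipeline to indeterminate
  calls (where expression is required) with a warning rather than
  aborting.

## Problem sizes used by the test-suite runs

The shipped tests run the bootstrap at 20–100 replicates on families of
10–20 sequences of 120–300 columns, the distance-oracle comparison on 200
random pairs of length 150, NJ enumeration oracles at 5–6 taxa with
direct recovery checks to 8 taxa, and the end-to-end scenario at its
default size. These sizes were chosen so the whole suite documents the
behaviour of every stage in about two minutes; all of them scale up
linearly through the same interfaces (the study-scale setting of 1000
bootstrap replicates is the `replicates` default of
`bootstrap_support()`).

## Known limitations

* Orthogroup cutting is a principled approximation; it does not reproduce
  by-eye clade naming in pathological topologies (low support everywhere,
  or heavy copy-number variation inside a lineage).
* The tandem rule ignores synteny; a translocated copy adjacent by rank
  would be linked where a collinearity tool might not link it.
* The built-in element consensi beyond CAAT-box are conventional
  PlantCARE-style choices, not study-reported strings.
* MW/pI match the ExPASy conventions; other tools (e.g. monoisotopic
  masses, different pK sets) will differ slightly.
* The per-species totals of the original genome-wide screen depend on
  external databases and manual curation and are carried only as a
  transcribed fixture, not recomputed.
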