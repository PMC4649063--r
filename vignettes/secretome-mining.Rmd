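---
title: "Methods: predicting, annotating and comparing fungal secretomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting, annotating and comparing fungal secretomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretominer)
```

# The model

`secretominer` implements an in-silico comparative secretomics workflow
for multi-species fungal genome sets. Its unit of observation is the
predicted classical secretome: the set of proteins carrying an N-terminal
signal peptide and no feature that retains them in a membrane or
organelle. Everything downstream — functional categories, small secreted
protein (SSP) mining, identity clustering, lifestyle partitioning and the
associated statistics — operates on that predicted set. Proteins exported
by unconventional, leaderless routes are invisible to this model by
construction; that is a stated limitation, not an oversight.

## The secretion decision rule

Each protein is scored on five independent sub-criteria, and is predicted
secreted exactly when all five pass:

* `sp_present` — a signal peptide was called, with a cleavage position
  (stored as the last residue of the signal peptide).
* `tm_ok` — the transmembrane topology is compatible with secretion:
  either no predicted helix, or exactly one helix whose start lies at or
  before the cleavage position. The geometric definition of "overlapping
  the signal peptide" had to be fixed here: the cleavage position is the
  only signal-peptide boundary available from short-format predictor
  output, so helix start ≤ cleavage position is used. A single helix
  situated after the cleavage site is a genuine membrane anchor and
  disqualifies the protein; two or more helices always do.
* `targetp_ok` — the targeting predictor assigns the secretory pathway
  (location code `S`; `M` and everything else fail).
* `wolfpsort_ok` — the sorting predictor ranks the extracellular
  compartment (`extr`) first. The tool reports an ordered list of
  compartment/score pairs without a score rule for "extracellular", so
  the top rank is used; ties at rank one pass when `extr` is among the
  tied labels, since the prediction does not prefer any other compartment
  over extracellular in that case.
* `kdel_ok` — the C terminus does not match an ER-retention tetrapeptide.
  Two motif modes are exposed: the literal `KDEL`, and the PROSITE-style
  class pattern `[KRHQSA]-[DENQ]-E-L` (accession PS00014). The class
  pattern is the default because it subsumes the literal motif while
  catching the common HDEL/RDEL variants; the choice is logged in every
  output header and is one flag away.

All five outcomes are recorded for every protein even when an earlier one
fails, so decision logs are complete and the rule is a pure conjunction —
a property the test suite checks exhaustively over all 2^5 combinations,
together with monotonicity (repairing a failing criterion can never turn
a secreted call off).

SSPs are secreted proteins with precursor length strictly below 300
residues. The threshold applies to the full precursor, signal peptide
included, because the length convention of the upstream gene catalogues
is precursor length; it is a parameter (`ssp_threshold`) everywhere.

## Evidence input, and a word on the surrogate predictor

The pipeline does not run any localization predictor. It parses the
standard short-output dialects of the four tools (signal peptide,
transmembrane topology, targeting, sorting) into one evidence table,
excluding — with a warning — proteins missing from any input, since an
incomplete evidence row cannot support the conjunction. For
self-contained demonstrations a deterministic heuristic surrogate is
included: it calls signal peptides from sequence anatomy (a K/R within
the first five residues, then ≥ 8 consecutive hydrophobic residues
within the first thirty, then an A-x-A cleavage context) and
transmembrane helices from 19-residue Kyte–Doolittle windows above mean
hydropathy 1.6. The surrogate is deliberately simple, is labelled
non-equivalent to the trained tools, and is never used where ground-truth
evidence exists.

## Functional categories

Annotation is table-driven: the user supplies pre-computed
similarity-search hits (`protein_id`, `database`, `subject_label`,
`evalue`, `bitscore`) against CAZyme, peptidase (MEROPS), lipase and PFAM
references. Per database the best hit at e-value ≤ 1e-5 (inclusive) is
kept, with ties broken by larger bitscore then lexicographic label so the
result is order-independent. The protein's category follows the database
of the overall smallest e-value among CAZy/MEROPS/LED; proteins with no
database hit are SSP (if small) or Other. The SSP flag is additionally
kept independent of the category, so a small lipase counts in both views.

The endo/exo protease split covers the ecologically relevant MEROPS
families: endo A01, M36, S53, S28; exo S08, S09, M28. Published accounts
of this split disagree among themselves about S08/S09/S28, so the mapping
is a plain configuration object (`default_protease_mapping()`) rather
than a constant — the alternative assignment is one edit. Families
outside the mapping are reported `unassigned`, never silently dropped,
and endo + exo + unassigned always partitions the annotated proteases.

K/R-rich regions are reported as maximal unions of 20-residue windows
with ≥ 40% K+R. The feature itself is standard; its parameterization is
not fixed by any convention we know of, so both knobs are exposed and the
defaults are stated here once: window 20, fraction 0.4.

## Identity clustering of SSPs

Pairwise identity is computed from an optimal global alignment under
BLOSUM62 with affine gaps (open 10, extend 1), as identical aligned
residue pairs divided by the length of the shorter sequence — the
convention of the classic greedy incremental clustering tools, whose
behaviour this module reproduces at desk scale without the heuristic
pre-filters. The denominator is switchable to alignment length. The
ambiguity residue X is accepted everywhere and never counts as a match.

Clustering is greedy and incremental: sequences sorted by decreasing
length (ties by identifier), each joining the earliest-created cluster
whose representative it matches at ≥ 70% identity, else founding a new
cluster. Representatives are therefore always longest members, cluster
ids number creation order from 0, and the documented sort plus tie-breaks
make the output invariant to input order — a property tested directly,
along with threshold monotonicity and, on random sets, a brute-force
verification of the first-fit membership rule. No k-mer pre-filter is
applied: at the scales this package targets, exact alignment against
representatives is fast, and a pre-filter could only change results.

Species-specific SSPs are those with no sufficiently strong local
alignment to any SSP of another species. Strength is judged by converting
the Smith–Waterman score to Karlin–Altschul bits
(`bits = (λS − ln K)/ln 2`, gapped BLOSUM62 constants λ = 0.267,
K = 0.041) and applying an e-value cutoff of 1e-5 over the actual search
space (query length × total other-species residues). This plays the role
a heuristic database search would at genome scale; intra-species hits are
ignored by definition of the quantity.

## Lifestyle partitioning and statistics

For the four-group comparison, registry lifestyles map onto ECM, white
rot, brown rot and soil/litter decayers; orchid and ericoid symbionts,
endophytes, pathogens, mycoparasites and yeasts map to `other` and sit
outside the four-set regions. A cluster's region is the exact set of
declared groups among its member species; its specificity is ECM-only,
saprotroph-only, shared-ECM-saprotroph, or other (any cluster touching an
out-of-scope lifestyle). Venn counts are conservative: every in-scope
cluster lands in exactly one region.

PFAM enrichment per lifestyle uses a one-sided Fisher exact test on the
2×2 table (in-lifestyle vs elsewhere × has-domain vs lacks-domain) over
secreted proteins, computed as the hypergeometric upper tail, with Holm
adjustment at α = 0.01. The test and correction are not dictated by any
single convention for this table; Holm at 0.01 was chosen to match the
correction and significance level used for the package's other group
comparisons, and both are parameters. Degenerate tables (a zero margin)
return p = 1 rather than erroring. Unit tests cross-check the tail
against `fisher.test`, and the acceptance suite against direct summation
of the hypergeometric pmf over all tables with margins ≤ 30.

SSP proportions (percent of secretome) are compared across lifestyles
with at least five member species, using pairwise Welch t-tests and
pairwise Wilcoxon rank-sum tests, both Holm-corrected, at α = 0.01.
Compact significance letters are derived from the maximal cliques of the
"not significantly different" graph. The Wilcoxon tests use the normal
approximation so tied percentages (common with small secretomes) do not
error. Secretome-vs-proteome size correlations are Pearson r and r² per
lifestyle with ≥ 3 species; zero-variance groups report missing values.

# The synthetic generator

The generator emulates the statistical shape of a multi-species fungal
genome survey so that every stage has planted ground truth. Its defaults
are the study conditions the package models: 49 species whose lifestyle
labels follow the packaged registry, proteomes of 10,000 genes, 6.5% of
each proteome carrying a signal peptide (surveys of this kind report
3–10%), just over half of secreted proteins below the SSP threshold, 15%
membrane proteins with 1–7 planted helices, and 2% of signal-peptide
proteins ER-retained by a C-terminal KDEL. Tests and examples pass
smaller explicit sizes — typically 2–6 species of 120–2,500 proteins —
chosen so the whole suite exercises every code path at desk scale; those
sizes are stated in the tests themselves.

Counts are planted exactly (rounded), not sampled, so recovery tests are
sharp: the decision rule applied to the emitted evidence must reproduce
the planted secretome identically, and it is tested to. Chance
ER-retention motifs arising in non-retained sequences are scrubbed
(C-terminal residue replaced) to keep the ground truth consistent.
Background residues are uniform over the 20 standard amino acids by
default — identity statistics under the null are easiest to reason about
that way — with a Robinson–Robinson-style frequency table selectable. All
randomness flows from one integer seed through per-species substreams, so
regeneration is byte-stable.

## Planted SSP families and identity calibration

Cross-species SSP families are planted by mutating a common ancestor
independently per member, with no indels. The per-site substitution rate
is calibrated so that the **expected pairwise identity between members**
equals the requested `family_identity`: under uniform substitution two
members agree at a site with probability `t² + (1−t)²/19`, where `t` is
the per-member retention, and `t` is solved from that equation. The
pairwise quantity is the one the clustering threshold sees, so
calibrating it (rather than the member-to-ancestor identity, which would
put pairwise identity near the square of the target and, at 0.85, within
noise of the 0.70 threshold) is what makes "family identity above the
clustering threshold" mean "recoverable by design". With that
calibration, families planted at 0.85 are recovered as single clusters
essentially always, and independent random ancestors of ≥ 80 residues
never merge — both properties are measured over 20 seeds in the
acceptance suite. Realized pairwise identities are returned with every
planted family.

When a family's lifestyle pattern repeats a label, distinct species of
that lifestyle are drawn, one member per species; a pattern demanding
more species of a lifestyle than exist is an error, not a silent
duplication.

Reference hit tables are generated the same way: exact per-species counts
of CAZyme/protease/lipase proteins receive a matching best hit below the
e-value cutoff, and PFAM accessions from a pool are scattered over
secreted proteins at a background rate, with per-(lifestyle, accession)
multipliers for enrichment experiments. With all multipliers at 1 the
Holm-corrected enrichment scan shows type-I control at or below twice the
nominal α over 200 simulation seeds; a 10× multiplier at 500 secreted
proteins per lifestyle is detected as the top enrichment.

## What the generator does not emulate

No phylogenetic structure (members diverge star-like from the ancestor,
without rate heterogeneity or indels), no compositional bias along the
sequence, no correlation between secretome size and proteome size, no
annotation noise in the evidence tables. Passing tests on synthetic data
therefore demonstrate correctness of the pipeline's logic under its own
model, not predictor accuracy on real proteomes — the predictors
themselves are upstream of this package by design.

# Packaged fixtures and their quirks

Two plain-text fixtures ship with the package: the 49-species registry
(name, lifestyle, phylum, family) and the printed table of
lifestyle-shared SSP clusters with an abbreviation map. Three points are
worth stating:

* Abbreviated member names collide at the genus initial (Paxillus,
  Pisolithus, Piloderma, Pleurotus, Plicaturopsis, Phanerochaete,
  Punctularia all print as "P."), so expansion goes through an explicit
  abbreviation map — never prefix matching. The map also carries the
  spelling variants that appear in the printed table, and the loader
  errors on anything it cannot resolve against the registry.
* The registry as printed contains 40 Basidiomycota and 7 Ascomycota
  species (plus one Chytridiomycota and one Zygomycota). Prose summaries
  of the same survey circulate slightly different phylum and group
  counts; this package always recomputes group sizes from the registry
  and never hard-codes them.
* The cluster table contains 17 ECM-only clusters (6 without a PFAM
  domain), 5 clusters shared between ECM and saprotrophic species, and 3
  saprotroph-only clusters; the lifestyle partition recomputed from the
  member lists agrees with the printed section headings, and that
  agreement is a test.

# Numerical and design choices, in one place

* E-value cutoffs are inclusive (a hit at exactly 1e-5 is kept).
* Identity denominator: shorter sequence (default) or alignment length.
* Greedy order: length descending, then identifier; first-fit membership;
  0-based cluster ids in creation order.
* Retention motif default: PS00014 class pattern; strict KDEL by flag.
* Endo/exo mapping and lifestyle grouping are configuration objects.
* Enrichment: one-sided hypergeometric tail, Holm, α = 0.01, proteins
  with the domain in fewer than 2 secretome proteins are not tested.
* Group comparisons: Welch t (no pooled SD), normal-approximation
  Wilcoxon, Holm, α = 0.01, lifestyles with ≥ 5 species.
* All output tables carry their thresholds as `#` header lines and
  re-read exactly.

# Limitations

Unconventionally secreted proteins are out of reach of the decision rule.
The surrogate predictor is a demonstration device, not a replacement for
the trained tools. The species-specificity criterion is a scored-alignment
surrogate for a database search and will differ from a heuristic search
engine near the cutoff. Clustering is exact but quadratic in the number of
SSPs per new representative, which is fine for tens of thousands of
sequences and was not engineered beyond that.
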