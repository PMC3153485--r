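---
title: "Classifying RelA/SpoT-homolog superfamilies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying RelA/SpoT-homolog superfamilies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

RelA/SpoT homologs (RSHs) synthesize and/or hydrolyse the alarmone ppGpp
that triggers the bacterial stringent response. The superfamily is defined
by two catalytic domains — a ppGpp synthetase (SYNTH) domain and a ppGpp
hydrolase (HD) domain — that occur together in the long, multi-domain RSHs
(with C-terminal TGS/helical/CC/ACT regions) or alone in the Small Alarmone
Synthetases (SAS, SYNTH only) and Small Alarmone Hydrolases (SAH, HD only).
Square-bracket nomenclature records the catalytic complement per protein,
lowercase marking a degraded (inactive) domain: `[HS]` is a bifunctional
enzyme, `[hS]` a RelA-like protein whose hydrolase domain has decayed,
`[S]`/`[H]` the single-domain classes.

Classifying a set of proteomes into RSH subfamilies involves a pipeline of
standard ingredients — profile-HMM search, E-value calibration, staged
filtering, distance phylogenetics, consensus analysis, rate-shift
statistics — whose decisions interlock. `rshkit` implements that pipeline
as a tested, reusable package, and ships a synthetic-superfamily generator
with complete ground truth so that every stage, and the pipeline end to
end, can be validated without any external database.

# Profile HMMs and E-values

`build_hmm()` estimates a local profile HMM from a multiple alignment.
Columns with gap fraction strictly below 0.5 become match states, mirroring
the alignment-trimming rule used throughout (`trim_gappy_columns()`);
emissions and transitions are maximum-likelihood counts smoothed with one
pseudocount spread over the background (emissions) or a uniform prior
(transitions).

The architecture is deliberately simpler than HMMER's Plan7:

* uniform local entry `B -> M_k` with probability `1/M`;
* position-dependent exit `M_k -> E` with probability `1/(M - k + 1)`
  (so the expected alignment end is uniform and `M_M` always exits),
  the remaining mass scaling the estimated `M -> {M, I, D}` moves;
* one shared insert-emission distribution (the background);
* interior deletions, with `D_M` exiting at probability 1;
* single-hit only; flanking residues are free.

Scores are log2 odds of the matched core against the background
(`viterbi()` for the best path, `forward()` for the path sum; both
implemented in C++ and checked against exhaustive path enumeration on all
models with up to 4 match states). No numerical compatibility with HMMER
scores is claimed; HMMER-style E-value gates are used as decision
semantics, not as score-for-score reproduction.

E-values come from an explicit Gumbel calibration (`calibrate()`): the
Viterbi scores of 200 i.i.d. background sequences of length 250 are fitted
by maximum likelihood, and

`E(S) = N * (1 - exp(-exp(-lambda * (S - mu))))`

for a search over `N` sequences. Model comparisons inside the pipeline use
the natural-log E-value, which remains well defined where the linear-scale
value underflows to zero.

# The staged gates

The pipeline applies its staged thresholds, all exposed in
`pipeline_config()`:

| gate | value | role |
|---|---|---|
| gathering | E <= 1e-2 | collect candidate family members |
| phylogeny | E <= 1e-5 | only reliably alignable sequences enter trees |
| final SYNTH | E <= 1e-4 | remove spurious synthetase-domain hits |
| final HD | E <= 1e-5 | remove spurious hydrolase-domain hits |
| fragments | length >= 100 | drop truncated sequences before phylogenetics |
| model span | >= 0.4 of match states | reject partial, spurious matches |

Rather than enumerating known false-positive families by name, spurious
hits are controlled generically by the stricter final thresholds plus the
minimum model-span fraction. All boundaries are strict in the stated
direction: a 99-residue sequence is removed and a 100-residue one kept; a
column at exactly 50% gaps is dropped.

# Iterative subfamily refinement

`iterative_classify()` repeats, for at most 3 rounds (the search converges
when the labels stop changing, which in practice happens by round 2):

1. build/recalibrate domain HMMs from the current member alignments (the
   user-supplied seed alignments in round 1);
2. scan every proteome at the gathering threshold; drop fragments;
3. align members at the phylogeny gate in the *profile frame* (one column
   per match state, deletions as gaps) and trim gap-rich columns. With the
   simulator's indel-free sequences this anchoring is exact; a de novo
   aligner is intentionally out of scope;
4. build an NJ tree with bootstrap supports per catalytic domain and
   extract subgroups (below); synthetase-carrying proteins are classified
   on the SYNTH-frame tree, hydrolase-only proteins on the HD-frame tree;
5. build a profile HMM per subgroup with at least 4 members and reassign
   every member to its best subgroup model by E-value. Members passing the
   final thresholds but falling in no qualifying subgroup are binned as
   `divSYNTH`/`divHD`.

# Distance phylogenetics and subgroup extraction

Distances are Poisson-corrected mismatch fractions over mutually non-gap
columns, `d = -ln(1 - p)`, with saturated pairs (`p >= 0.95`) capped at
`d = 10` with a warning. Trees are neighbor joining (negative branch
lengths clamped to zero), midpoint rooted; supports are the percentage of
100 column-resampled replicates containing each bipartition. Rows are
sorted canonically first, so supports do not depend on input order.
Distance-based NJ with bootstrap deliberately stands in for
maximum-likelihood and Bayesian inference here: subgroup recovery, not
branch-length accuracy, is what the downstream steps consume.

`extract_subgroups()` walks the rooted tree top-down and emits a clade as
a subgroup when support >= 60, size >= 4, and mean intra-clade path
distance is at most half the tree-wide mean (the compactness knob).
Because that criterion is purely relative, the sub-clades of a single
homogeneous family would eventually qualify and split it; emitted groups
are therefore merged when they are not genuinely separate subfamilies.
The primary merge signal is the defining property of these subgroups —
orthologous subfamilies have single representatives per genome — so two
groups drawn from (nearly) disjoint genome sets are sub-clades of one
cluster and are united, guarded by a stem-versus-crown cap (the stem
separating the pair must not exceed 2.5 crown lengths) so that genuinely
distant groups with complementary genome coverage are never merged. True
paralogous subgroups co-occur in the same genomes and never trigger the
rule. Without a genome mapping, only a conservative stem rule (1.5 crowns)
is applied.

# Architectures, activity and complement rules

Per protein, overlapping final hits are resolved by lowest E-value (ties:
higher bit score, then model name); class follows domain content (long /
SAS / SAH) and the bracket nomenclature lists H/S in N-to-C order.

A domain hit is called *degraded* when either

* its bit-score density (bits per match state) falls below half the median
  density of all final hits for that domain, or its model-span fraction is
  below 0.6 — the per-hit rule; or
* its subgroup's clade-level divergence flags the domain (below).

The clade-level rule matters because iterative retraining teaches the
family HMM the degraded clade's own residues, pulling per-hit scores back
toward normal; the divergence signal — the inactive domain's branch
lengths — is robust to that. `domain_divergence_ratio()` computes, per
domain, the mean pairwise Poisson distance within the clade divided by the
mean over the *other* domains (leave-one-out, so the baseline excludes the
domain under test); a ratio above 2 is degraded-like. With the two-domain
case the all-domain mean would cap the ratio at 2, which is why the
baseline is leave-one-out.

`genome_complement()` tabulates per-genome subgroup counts and class
totals, and `check_complement_rules()` applies the organisational rules:
an active synthetase with no active hydrolase anywhere in the genome is
flagged as a violation (unchecked alarmone synthesis is lethal, and no such
natural genome is observed), while hydrolase-only and RSH-free genomes are
allowed.

# Conservation analytics

`consensus()` implements percentage-similarity consensus at a threshold in
(0.5, 1]: per column, a residue strictly exceeding the threshold among
non-gap rows wins (uppercase); otherwise a physicochemical class
(lowercase representative); otherwise `-` if the column is mostly gaps,
else `x`. The comparison is strict so that 7 of 10 rows do not clear the
0.70 default while a fully agreeing class does. The class partition is a
Dayhoff-like one — {AGST}, {ILMV}, {FYW}, {KRH}, {DE}, {NQ}, {C}, {P} —
stated explicitly because "percentage similarity" is undefined without it;
it is a declared choice, not a reconstruction of any particular script.

`classify_column_conservation()` reproduces the comparative categories
used when reading subgroup consensus alignments side by side: UNIVERSAL,
DISTINCTIVE_FOCAL (the focal subgroup conserved against a different or
absent consensus elsewhere), PAIR_NOT_X (all but one subgroup agree), and
UNCONSERVED. `find_group_specific_sites()` returns columns conserved in an
in-group and unconserved in an out-group at the same threshold; the
contrast is sharpest when the out-group is a single orthologous cluster,
since the union of distant paralog groups dilutes its own consensus.

# Functional divergence

**Type I** (rate shifts). Analyses of this kind are often delegated to
the DIVERGE program; `rshkit` uses a self-contained Poisson-count reformulation with the same
decision semantics. Per column and clade, `fitch_counts()` gives the
parsimony minimum number of substitutions (gaps as missing data; the count
is root-invariant and tested against brute-force labelings). For clades A
and B with tree lengths `T_A`, `T_B`, a site's counts are Poisson with
mean `r * T`; rates are gamma-distributed with shape 1 (exponential) by
default. With probability `1 - theta` the two clades share one rate, with
probability `theta` they draw independent rates. Both marginals are closed
form (gamma-Poisson), and `theta` plus the rate scale are estimated by
maximum likelihood; sites with posterior probability of the divergent
component >= 0.90 are flagged. The standard error of `theta` comes from
the observed information via the delta method.

Power depends on the counts: deep, sparsely sampled clades saturate
parsimony and wash the shift out. The validation regime
(`simulate_rate_shift_pair()`): two clades of 24 leaves at root-to-tip
depth 0.35, 200 columns, 15% of sites shifted 5-fold — recovers
`theta` to within 0.1 and flags sites with precision near 1.

**Type II** (fixed radical differences). `type2_sites()` returns columns
where each clade is fixed on one residue at frequency >= 0.95, the
residues differ, and they lie in different physicochemical classes. The
0.95 tolerance implements "completely fixed" while allowing the odd
dissenting sequence. The EXDD/RXKD-like specificity motif is the canonical
case: `specificity_motif()` maps `E-x-D-D` to GDP preference and
`R-x-K-D` to GTP preference.

# The synthetic superfamily

`simulate_superfamily()` generates proteomes with complete truth. Each
subgroup root evolves from a family root along a backbone branch (0.6
substitutions/site), then members evolve along a shared Yule genome tree
(root-to-tip depth 0.15). Site substitution counts are Poisson in rate x
branch length; replacements are class-biased (within-class moves 4x more
likely), making radical substitutions the exception, as in real proteins.
There are no indels: architectures change only by whole-domain loss, so
the true per-domain alignments are exact — this is what makes
profile-anchored alignment lossless and keeps an external aligner out of
scope.

Site rates are gamma with shape 0.5, the empirically typical regime for
protein domains: conservation is strongly bimodal (near-invariant
structural sites, fast surface sites) with few columns hovering at the
0.70 consensus threshold, which is what makes threshold-based consensus
calls reproducible. Columns planted as "conserved only in" a set of
subgroups are held invariant there and given a floor rate of 8x the mean
elsewhere — class-biased replacement keeps class-level support above 0.70
until more than about one substitution per site has accumulated, so the
floor must be high for the planted contrast to be structural rather than
left to the draw.

The reference configuration (`reference_config()`, seed 42) fixes the
study conditions used by the tests and the acceptance script: 20 genomes;
six subgroups — three long (HD+SYNTH+TGS+ACT; one with its HD degraded
4-fold and the EXDD-type motif, one with a 15%/5x SYNTH rate shift, both
others RXKD), two SAS, one SAH; domain lengths SYNTH 113 (the synthetase
domain's mean length), HD 168, TGS 60, ACT 60; three decoys per genome
(i.i.d. background residues, 120-400 aa); 10% truncated (<100 aa)
fragment copies; and one genome (`g20`) carrying only a SAS, the
engineered complement-rule violation.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: insertions and deletions (real alignments need
an MSA engine and their profile columns are uncertain), compositional
biases and empirical substitution matrices, domain-order rearrangements,
horizontal transfer (every subgroup follows one genome tree), taxonomic
structure, and sequencing/annotation noise beyond simple truncation.

# Numerical and determinism choices

* All DP is in log2 space with `-Inf` as the impossible-path sentinel;
  probability bundles are validated to sum to 1 within 1e-9 after build
  and serialization round trips.
* Every stochastic step (tree simulation, evolution, calibration,
  bootstrap) takes an explicit seed; derived seeds are deterministic
  functions of the master seed and a stage tag, kept below 2^31. RNG state
  is restored after each seeded block, so library calls do not perturb the
  caller's stream.
* Orderings that feed output files use locale-independent radix sorting;
  two runs with the same inputs and seed produce byte-identical JSON.
* Viterbi ties resolve in a fixed preference order (entry, match, insert,
  delete); overlap resolution and subgroup naming break ties
  lexicographically.
* Saturated distances are capped (`d = 10`) rather than infinite; NJ's
  occasional negative branch lengths are clamped to zero.

# Problem sizes

The validation suite runs the full pipeline on the 20-genome reference
superfamily (186 proteins, about a minute), 50 NJ exactness instances at
4-8 taxa, exhaustive HMM-path enumeration up to 4 match states and
5-residue sequences, brute-force Fitch on 6-leaf trees, and 10 replicates
of the 24-leaf rate-shift regime. These sizes were chosen so the whole
suite gives sharp answers in a few minutes on one core; all of them are
plain function arguments and scale up directly.

# Known limitations

* The profile HMM is single-hit: a protein with two copies of the same
  domain yields one envelope. Repeat architectures would need a multi-hit
  grammar.
* Gumbel calibration from 200 background samples gives E-values accurate
  to well within the order of magnitude the gates require, but tail
  estimates beyond that are extrapolation.
* Subgroup extraction assumes subgroups are ortholog-like clusters; a
  genuine paralog expansion inside one genome weakens the genome-overlap
  merge signal (the stem guard still applies).
* The type I model fixes the gamma shape at 1 for rates within the count
  model (configurable); it estimates one shared rate scale for both
  clades, so global rate differences between clades are absorbed into tree
  lengths, not detected as divergence.
* With no indel process, the package never exercises alignment-uncertainty
  failure modes; on real alignments the profile frame inherits whatever
  the upstream MSA got wrong.
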