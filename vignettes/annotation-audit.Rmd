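---
title: "Auditing enzyme-class annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing enzyme-class annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecaudit)
```

# The audit in one paragraph

Given the sequences annotated to an enzyme class and the subset with
experimental characterisation, `ecaudit` asks, for every sequence: does
anything experimentally grounded actually resemble it? Two orthogonal
signals answer that. The first is the percent identity to the closest
characterised sequence, found with a cheap alignment-free prefilter and
confirmed by global alignment; below ~25% identity (the "twilight zone")
functional transfer between homologues is unreliable, so such sequences
are unlikely to be annotated on real evidence. The second is the domain
architecture: a sequence whose domain content differs from every
architecture seen among characterised members probably catalyses a
different reaction altogether. The audit reports both flags per sequence
and as class-level fractions, the second one being the headline
misannotation estimate.

# Pipeline stages and their parameters

## Input cleanup

Sequences shorter than **200** or longer than **580** residues are
removed, as are sequences containing the ambiguity letter `X`
(`filter_spec()`). These bounds bracket the typical length of a
single-domain flavin-dependent oxidase and exclude fragments and fusion
artefacts that would degrade alignments. Each removed sequence is counted
under one reason (too short, then too long, then ambiguous). Exact
duplicate sequences are collapsed to the first-seen accession;
characterisation is treated as evidence about the *sequence*, so the
retained record is characterised if any duplicate was.

## Alignment-free prefilter

Profiles of overlapping k-tuples with word size **k = 3** (windows
containing `X` are skipped) feed a set-based adaptation of the normalised
Google distance: with `f(p)` the distinct word count of profile `p`,
`f(p,q)` the shared distinct words, and `N` the corpus-wide distinct word
count,

$$d(p,q) = \frac{\max(\log f(p), \log f(q)) - \log f(p,q)}
                {\log N - \min(\log f(p), \log f(q))}$$

clamped to [0, 1], with `d = 1` when no word is shared and `d = 0` for
identical word sets. The clamping and edge policies are pinned so the
distance is deterministic; the measure is only ever used to *rank*
candidates, never as a calibrated quantity. `rank_agreement()` measures
how well this ranking agrees with alignment identity (Spearman's rho on
all pairs); on a 50-sequence mutational ladder the suite observes rho
well above 0.9, which justifies aligning only the top-ranked candidate
(`top_n = 1`) by default. `top_n` is configurable upward because a top-1
prefilter can in principle miss the true best hit; with
`top_n = |characterised|` the search provably equals the exhaustive
maximum, which is how the test suite oracles it.

## Global alignment and percent identity

Pairwise comparisons use Needleman–Wunsch global alignment with affine
gaps, scored by **BLOSUM62** with gap opening **−10** and extension
**−0.5** per position (a gap of length L costs `10 + 0.5·L`). The engine
is `Biostrings::pairwiseAlignment`; the test suite verifies its optima
against an independent exhaustive enumeration of all alignments on short
sequences. Percent identity is defined as

$$\mathrm{pid} = 100 \cdot \frac{\text{columns with identical non-gap
residues}}{\text{all alignment columns (gap columns included)}}$$

This is the conservative convention — terminal and internal gaps dilute
identity — and it is applied uniformly, so the 25% threshold always means
the same thing. Alignment column counts are recovered from match/mismatch
tallies (`columns = L_a + L_b - \text{aligned pairs}`), which the suite
checks against direct column counting.

## Clustering

Two routes, serving different purposes:

* **MCL** (`mcl()`) clusters the class for representative selection. The
  similarity graph is built internally from all-vs-all alignment scores
  clamped at zero — unrelated pairs get negative global scores and hence
  no edge, mirroring the absence of a BLAST hit — or from a user-supplied
  BLAST tabular file. The algorithm is pinned precisely because MCL
  variants differ: self-loops at each node's maximum incident weight,
  expansion by matrix squaring, inflation **1.4** (elementwise power,
  columns renormalised), pruning below 1e-5, convergence when the matrix
  changes by less than 1e-8, clusters read as connected components of the
  limit matrix's support, representatives by highest degree with
  lexicographic tie-break.
* **Greedy identity clustering** (`greedy_identity_cluster()`) reduces
  redundancy before a class-wide audit, emulating CD-HIT's longest-first
  logic at a **90%** identity threshold with a shared-word prescreen at
  word size **5** — but computing true alignment identity rather than a
  word-based approximation, preferring correctness over speed at the
  scale this package targets. Because clustering keeps only
  representatives, characterised members swallowed by a cluster are added
  back (`restore_characterised()`) so the audit never loses evidence.

A consequence worth stating: greedy clustering at threshold *t* can only
merge sequences at ≥ *t* identity to their cluster founder, so planted
families are recovered exactly only when within-family identities sit
comfortably above *t*. The clustering-recovery checks therefore use
families generated at 97–100% identity to the root (pairwise ≳ 94%) — for
looser families the reduction intentionally yields several clusters per
family, which is correct behaviour for its redundancy-reduction purpose.

## Representative selection

Within each cluster, sequences are aligned (see below) and representatives
chosen to cover the alignment's variability. The per-column Shannon
entropy `H_j = -Σ_a p_{j,a} log2 p_{j,a}` is computed over the residue
symbols **plus the gap symbol** — gaps are treated as informative because
indel patterns track cluster substructure. The objective for a subset `S`
of rows is the entropy-weighted coverage

$$E(S) = \frac{\sum_j H_j \, c_j(S)}{\sum_j H_j}, \qquad
  c_j(S) = \sum_{a \,\in\, \text{symbols of } S \text{ at } j} p_{j,a}$$

i.e. each column contributes its entropy, weighted by how much of the
column's symbol mass the chosen sequences exhibit. This operationalisation
of "information explained" was a genuinely open design point; this form
was chosen because it is monotone and submodular (so greedy selection is
principled), equals 1 on the full set, and reduces to the intuitive
answer on degenerate inputs — an alignment of identical sequences is fully
explained by any single row. Selection is greedy: repeatedly add the row
with the largest marginal gain (ties to the lowest row index) until
**85%** of the information is explained. Greedy maximisation of a
submodular objective is optimal for the first pick and within a
`1 − 1/e` factor thereafter; the suite confirms `k = 1` optimality
exactly and measures how often the two-step greedy set matches the
exhaustive best pair — it does not always, and that gap is an inherent
property of greedy selection under this objective, not a defect of the
implementation.

For internal use the per-cluster alignment is a centre-star construction:
every sequence is globally aligned to the longest member and the pairwise
alignments are merged under the once-a-gap-always-a-gap rule. This avoids
any external alignment binary and is adequate for entropy bookkeeping
within a cluster of related sequences; any externally computed alignment
can be supplied as aligned FASTA (`read_msa()`) when alignment quality
matters more.

## Misannotation flags

* **Identity flag**: `below_threshold` is *strictly* below **25%** — a
  sequence at exactly 25.0% is not flagged.
* **Architecture flag**: architectures are compared as **multisets** of
  domain labels. "Same domains, any order" is ambiguous between set and
  multiset semantics; multiset is the stricter reading and catches domain
  duplications, which are real architectural differences. Records with
  unknown (empty) architectures are scored non-canonical per record but
  **excluded from the denominator** of the class-level fraction by default
  (`include_unknown = TRUE` overrides), because a missing architecture
  often reflects a partially sequenced gene rather than a different
  protein.
* **Conserved residues** (optional): specified positions of a reference
  enzyme are mapped through the global alignment; a reference position
  aligned to a query gap counts as not conserved, which is a scoring
  outcome rather than an error.
* Identity histograms use bins `[i, i+1)` for i = 0..99 plus a closed bin
  at exactly 100, per superkingdom, so self-matches of characterised
  sequences (100%) and sequences with no characterised homologue (0%) are
  visible as their own peaks.

## Screening and kinetics

The limit of detection is `mean(blanks) + 4·SD` with the sample (n−1)
standard deviation — the unbiased choice at three replicates. A protein is
a hit only if soluble in ≥ 2 of 3 expressions *and* active (control-
subtracted signal strictly above the LOD) in ≥ 2 of 3 assay replicates;
control subtraction retains negative values rather than clipping.
Absorbance slopes convert to molar rates through the extinction
coefficient (default 20.7 mM⁻¹cm⁻¹, DCPIP at 600 nm). Michaelis–Menten
fits are unweighted least squares via Levenberg–Marquardt
(`minpack.lm::nlsLM`), initialised at `V_max⁰ = max(v)` and `K_M⁰` at the
concentration whose velocity is nearest `V_max⁰/2`, with parameter
tolerance 1e-10 and non-negativity bounds; standard errors come from the
Jacobian. A fit is warned as "poorly constrained" when `K_M` leaves the
informative range `(max(S)/10^4, 100·max(S))` — the lower guard catches
the boundary fits that arise when all velocities are saturating and `K_M`
is unidentifiable.

# The synthetic generator

`generate_ec_class()` emulates the *structure* the audit assumes: one
canonical family holding all characterised members and a canonical
architecture, plus unrelated families with distinct architectures — the
planted misannotations. Family roots are drawn i.i.d. (uniform residues
by default; a natural-background option exists for more realistic
twilight-zone baselines) with rejection sampling enforcing pairwise root
identity below 30%. Members are produced by `mutate_to_identity()`, which
substitutes an exact count of positions (so the realised substitution
identity is analytically controlled) and then applies single-residue
indels at a small rate (default 0.01/site). Default dimensions: 100
sequences of root length 350 in five families (60/12/10/10/8), five
characterised, within-family identity 0.70–0.95, superkingdoms sampled at
roughly 91% Bacteria / 6% Eukaryota / 2.6% Archaea to mirror the strong
bacterial skew of real enzyme classes.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: phylogenetic correlation (no tree-based
evolution; all members radiate independently from a root), compositional
bias and low-complexity regions, domain-level evolution (architectures
are assigned, not emergent), alignment ambiguity at realistic identity
levels, and database noise such as fragments or chimeras beyond what the
length filter models. Results on synthetic classes certify the machinery,
not the biology.

# Determinism and problem sizes

Every stochastic step flows through explicit seeds; reruns of
`run_audit()` with the same inputs and seed produce byte-identical
artifacts. Tie-breaks (prefilter ranking, cluster representatives, greedy
selection) are pinned lexicographically or by index so results never
depend on input order — greedy clustering is additionally tested for
invariance under shuffled input. The test and acceptance workloads were
sized for a desktop run: audits of ~100 sequences of length ~350,
alignment-oracle checks on 200 short pairs, 50-fixture selection
comparisons, 100-draw kinetic Monte Carlo; the full suite and the
acceptance script each complete in about two minutes on one CPU.

# Known limitations

* The prefilter-then-align shortcut (`top_n = 1`) can understate the true
  maximum identity when k-tuple ranking and alignment identity disagree;
  raise `top_n` where that risk matters.
* The centre-star alignment is a heuristic; for publication-grade cluster
  alignments supply an external MSA.
* Greedy representative selection is not exhaustive-optimal beyond the
  first pick (see above).
* The MCL policy is one of several in circulation; results with other MCL
  implementations may differ at weakly connected nodes.
* `classify()` treats the characterised set as ground truth; a
  *mis*-characterised sequence would distort the audit, and nothing in
  the package can detect that.
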