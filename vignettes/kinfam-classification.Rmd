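---
title: "Classifying a two-lobe kinase superfamily into functional families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying a two-lobe kinase superfamily into functional families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinfamr)
```

## The problem and the model

A protein-kinase superfamily contains thousands of sequences built
around one catalytic unit — a small N-lobe and a larger C-lobe joined by
a hinge — embedded in widely varying multi-domain contexts. Sequences
that share the fold do not share function: subfamilies differ in
substrate, regulation and inhibitor response. The package's working model
is that a *functional family* is a set of relatives that (a) share a
multi-domain architecture history, and (b) are conserved at the same
alignment positions, while *differing in a consistent, conserved way*
from their nearest neighbours at a small number of positions — the
specificity-determining positions (SDPs). Classification therefore
proceeds bottom-up: resolve architectures, group near-identical
sequences, agglomerate by profile similarity, and cut the merge tree
wherever two branches show significant differential conservation.

This assumes the inputs are trusted domain hits (the package never runs
an HMM search itself), that functional divergence leaves a residue-level
signature, and that within-family variation is substantially smaller
than between-family divergence. Where those assumptions fail — families
separated by a single residue, or families whose members are more
divergent than their neighbours — the method will merge or split
accordingly.

## Stage by stage

### Architecture resolution

`resolve_hits()` solves the weighted-interval scheduling problem exactly
over the scored hits of one sequence: maximise total score subject to
pairwise non-overlap of closed 1-based intervals. Ties are broken toward
more hits, then the lexicographically smallest sorted
`(start, family_id)` list, so the result is a pure function of the hit
*set*. An exact solver was chosen over a heuristic trimmer because it is
oracle-checkable: the tests compare it against exhaustive subset
enumeration on hundreds of random instances.

`build_functional_units()` pairs each N-lobe with the nearest following
C-lobe when no other domain intervenes and the gap (the hinge linker) is
at most `linker_max = 20` residues. The 20-residue bound covers the
complete hinge while excluding lobe pairs that belong to different
catalytic units; tandem-kinase proteins (two N/C pairs in a row) resolve
into two units naturally under the nearest-following rule. Lobes that
cannot be paired form no unit and keep their own family token in the MDA
key; sequences whose only lobes fail the linker bound are excluded from
classification rather than concatenated across an arbitrary gap.

### Identity pre-clustering (S90)

Units are clustered greedily at 90% identity (global BLOSUM62 alignment,
affine gaps −10/−0.5, identities divided by the shorter sequence
length). Greedy first-fit with length-descending order mirrors standard
redundancy-reduction tools and guarantees that each member is within the
threshold of its representative. Cluster alignments are star alignments
against the representative — members are by construction near-identical
to it, so the star approximation is benign there.

### Profiles and the merge tree

Each cluster becomes a frequency profile: per-column residue
probabilities under position-based (Henikoff) sequence weights with
optional background pseudocounts. Profiles carry no insert/delete
states: their only role is to *rank merges*, and a plain
profile–profile dynamic-programming alignment preserves that ranking
while remaining fully checkable against a plain sequence DP in the
single-sequence limit.

Two numerical choices matter here:

* **Gap penalties and normalisation.** Column scores are
  `p_i' B62 q_j`; gaps open at −10 and extend at −1 (the first gap
  column costs −11). Totals are normalised by the shorter profile's
  column count, which makes the score symmetric and comparable across
  cluster sizes. The normalisation constant is a package choice; only
  the induced *order* of merges matters downstream.
* **Pseudocount mass in the pipeline.** `build_profile()` defaults to
  pseudocount mass 1.0, appropriate when a profile is used on its own.
  Inside the classification pipeline (`kinfam_params()`) the mass is 0:
  background smoothing shrinks small clusters toward the background and
  systematically depresses every score involving them, so with heavy
  smoothing two large clusters from *different* families outscore a
  singleton joining its *own* family, and the agglomeration strands
  singletons above the family cuts. With unsmoothed profiles the merge
  order is driven by membership, not cluster size.

Merging follows the profile alignment path (columns aligned, shared gap
columns inserted) rather than re-aligning members from scratch —
deterministic and cheap, at the cost of never revising early alignment
decisions. Score ties break on the lexicographically smallest id pair,
so the tree is invariant to input order (verified by permutation tests).

### Cutting the tree

At every internal node the two children are compared column-wise in the
node's joint alignment under the similarity kernel
`sim(x, y) = max(0, (B62(x,y) + 4) / (max(B62(x,x), B62(y,y)) + 4))`,
which maps BLOSUM62 into [0, 1] with `sim(x, x) = 1`. A column is an SDP
when both groups are conserved (`cons >= tau_cons = 0.8`), the
differential signal `groupsim = min(cons_A, cons_B) − between` reaches
`tau_gs = 0.4`, and neither group is more than half gaps (differential
conservation is ill-defined on mostly-gap columns; `X` counts as a gap
throughout). The thresholds are deliberately strict: 0.8 within-group
conservation tolerates roughly 1-in-5 divergent residues at 20 sequences,
and 0.4 groupsim requires the between-group similarity to fall well
below within-group levels, which excludes conservative (e.g. I/V)
between-family drift from being called specificity-determining.

`decide_cut()` keeps children separate when both have at least
`n_min = 3` members, both pass the information gate, and at least
`k_min = 2` SDP columns separate them. The information gate asks whether
a child's conservation estimates can be trusted: a child passes with
DOPs ≥ 70, *or* with at least `n_reliable = 6` members. The escape for
larger children is deliberate: low DOPs means most columns share the
same conservation value, which in a many-sequence alignment reflects
redundancy, not an inability to estimate conservation — it is the very
small clusters whose conservation (and hence SDP calls) are unstable.
Tying the hard DOPs requirement to children below six members keeps the
gate's purpose (don't split on unreliable signal) without vetoing every
split between well-populated, highly conserved families, which would
otherwise be the dominant behaviour at realistic within-family
conservation. Cuts propagate: once any descendant of a node is split,
the node never merges across that boundary.

`classify_superfamily()` runs the above per MDA partition, holds aside
clusters with no experimentally annotated member, pools the per-MDA
families, and repeats the merge/cut cycle once over the pooled families.
The final iteration is what lets one functional family that happens to
occur in two architectures re-join; pooled families enter as atomic
clusters (no fresh S90 round — the families are already
identity-coherent). Held-aside clusters are finally scored against every
family profile and reported with their best match, advisory only.

### Evaluation operations

* `conservation_score()` is the mean pairwise kernel similarity of a
  column's residues multiplied by the non-gap fraction; `dops()` is
  100 × (distinct conservation values, rounded to 4 decimals) / columns.
  Identical sequences give one distinct value (DOPs = 100/ncols);
  alignments whose per-column variability varies continuously approach
  100. The 70 threshold is used as the conventional marker of an
  information-rich alignment.
* `ec_purity()` counts distinct EC4 codes and their EC3 prefixes among
  annotated members; summary fractions exclude families with no EC at
  all, since absence of annotation says nothing about purity.
* `calibrate_evalues()` fits a Gumbel law by the method of moments to
  the scores of background-composition decoys and converts scores to
  E-values against a database of `n_db` sequences. Method-of-moments on
  200 decoys is crude but testable: at the decoy mean the exceedance
  probability is analytically 1 − exp(−exp(−γ)) ≈ 0.44, and the far
  tail at E ≤ 1e-18 must reject essentially all decoys while retaining
  family-consensus probes — both properties are asserted directly.
* `map_families()` labels each reference family one-to-one, split,
  merged or unmapped from plain set arithmetic over a sequence-level
  assignment (test partition first, scan hits as fallback).
* `family_enrichment()` uses the exact hypergeometric upper tail via
  `phyper` and Benjamini–Hochberg q-values via `p.adjust`; the drug
  filter applies the approved-phase, binding-assay, pChEMBL ≥ 6,
  activity < 1 mM and ATC "L01E" gates jointly, exactly as stated, even
  though the pChEMBL bound subsumes the activity bound. The enrichment
  universe is the set of classified sequences under analysis.

## What the synthetic generator emulates — and what it does not

`generate_superfamily()` plants the statistical structure the classifier
assumes: families drawn from one root consensus, conserved within,
differing between in two distinct ways.

* **SDP columns.** One global set of `n_sdp_columns` positions at which
  every family carries a distinct residue from a panel chosen for
  mutually *low* kernel similarity (max 0.42; the rotation over the
  panel keeps pairs at small family offsets below 0.24). These are
  radical substitutions — the signature of genuine specificity switches
  — and constitute the exact ground truth for SDP recovery.
* **Neutral drift.** With probability `between_family_divergence = 0.3`
  per eligible column, a family replaces the root residue with its
  conservative partner (kernel similarity ≥ 0.75: I/V, L/I). Real
  subfamilies are clades: they differ at many neutral positions, not
  only at functional ones, and neutral divergence is overwhelmingly
  conservative. This drift is what separates families in exact-match
  identity (so the S90 stage and the merge ordering behave as they do on
  real data) while remaining invisible to the SDP statistic, keeping the
  planted-SDP truth exact. Without it, families differing at only five
  columns would sit ~1.5% identity apart — inside the noise of the 90%
  threshold — and no identity-based seeding could separate them.
* **Within-family mutation.** Each residue mutates independently at
  `within_family_mutation_rate = 0.05`, with mutant residues drawn
  proportional to `bg(a)·2^(B62/2)` — the conservative spectrum of
  accepted point mutations — rather than uniformly.
* **Architecture and annotation structure.** Families are spread
  round-robin over the configured MDA layouts (default: bare unit,
  accessory-then-unit, unit-then-accessory); the hinge linker is drawn
  once per bundle as part of the shared consensus; every fifth sequence
  receives a weak spurious hit overlapping its C-lobe that resolution
  must discard; a fraction of sequences (default 10%) carries no
  annotation; drug targets (default 15% of sequences, 80% of them in the
  first family) come with fully qualifying ChEMBL-style records plus a
  handful of records that each fail exactly one filter gate.

Defaults are scaled to a desk-size study: 6 families of 18–22 sequences
(~120 total) over 3 architectures with 5 SDP columns, which the test
suite and acceptance script run across 20 seeds on one CPU in a few
minutes.

Deliberately **not** emulated: insertions and deletions within the unit
(disabled by default so alignment columns correspond one-to-one to unit
coordinates and SDP truth needs no coordinate mapping — an optional
realism the default tests trade away for exactness), real kinase motif
content (HRD/DFG motifs appear only in a small encoded test fixture),
heterogeneous site rates, phylogenetic correlation within families
(members are i.i.d. around the family consensus), and any real database
scale. Consequently, passing tests demonstrate that the machinery
recovers the planted structure under the stated noise model; they do not
certify performance on real superfamilies, where alignment error, indels
and uneven sampling add failure modes the fixtures exclude.

## Degenerate inputs and tie-breaking

Empty hit sets resolve to an empty architecture; architectures without
pairable lobes produce no unit and drop out of classification; columns
with fewer than two residues score conservation 0 and are never SDPs;
all-gap profile columns fall back to the background distribution;
single-cluster partitions skip straight through the tree stage; a
classification with zero annotated clusters is an error rather than a
silent empty result. All stochastic steps (generator, decoys,
calibration) take explicit seeds and restore the caller's RNG state; all
order-sensitive steps (greedy clustering, merge ties, resolution ties,
family ids) have documented deterministic tie-breaks, so every result in
the package is reproducible from its inputs and seeds.

## Known limitations

* The star alignment and path-following merges never revise early
  alignment decisions; with indel-rich real data a proper progressive or
  iterative aligner would be preferable.
* Profile scores have no statistical calibration at the merge stage
  (E-values exist only in the scan stage); merge ordering is therefore
  scale-dependent, though only the order matters.
* The SDP statistic compares exactly two groups; multi-way differential
  conservation is reduced to the pairwise comparisons the tree happens
  to present.
* Gumbel calibration by moments on 200 decoys gives E-values good to an
  order of magnitude at the extreme tail — sufficient for the 1e-18
  match rule, not for fine-grained ranking near the threshold.
* The enrichment test treats targets as exchangeable across the
  universe; family size confounding beyond the hypergeometric model
  (e.g. length or annotation-depth bias) is not modelled.
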