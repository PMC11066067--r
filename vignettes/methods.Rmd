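---
title: "Dated DTL reconciliation and gene-family chronologies: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dated DTL reconciliation and gene-family chronologies: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtlchron)
```

## The scientific problem

Incongruence between a gene tree and the species tree it evolved inside
records the gene's history: duplications, horizontal transfers and losses.
When the species tree is *dated* — every node carries an age in Ga — that
history can itself be dated, turning phylogenomics into a geological record:
the oldest inferred event for a family is the first phylogenetic evidence of
the gene's existence, a lower bound on its origin.  `dtlchron` implements the
full chain: homolog screening, posterior-sample summarisation, dated
parsimony reconciliation, event dating and period binning, plus a
present-day ecological anchor (gene abundance vs phosphate concentration in
ocean metagenomes).

## The reconciliation model

### Time slices

The distinct internal-node ages of the dated species tree, plus the present,
cut $[0, t_{\mathrm{root}}]$ into *time slices*.  A branch belongs to every
slice its age interval spans; two branches may exchange a gene by transfer
only within a slice they share.  This is the standard dated-DTL
discretisation: inside one slice the set of living lineages is constant, so
contemporaneity checks reduce to slice membership.  We use strict interval
overlap (a branch must span the whole slice); lineages that merely touch a
slice boundary do not count as contemporaneous, the conservative reading.

### Events and the dynamic program

For gene clade $u$, species branch $x$ and slice $s$, let $V_s(u, x)$ be the
minimum cost of embedding $u$'s subtree given its lineage occupies $x$ at the
top of $s$.  Moving down through the slice and across its bottom boundary,
the recurrence minimises over:

* **speciation** (cost $\sigma$) at the node ending $x$: the clade's two
  child clades descend into the two daughter branches, in either assignment;
* **speciation-loss** (cost $\lambda$): the clade passes through the node
  into one daughter branch, the other copy is lost — recorded as a single
  loss event;
* **duplication** (cost $\delta$) anywhere on $x$ within the slice;
* **transfer** (cost $\tau$): one child stays on $x$, the other is received
  by any other branch alive in $s$, or by the dead channel;
* **transfer-loss** (cost $\tau + \lambda$): the whole lineage jumps, the
  donor copy dies;
* **null passage** (free) across a slice boundary on the same branch.

The *dead channel* is one extra location per slice representing all unsampled
or extinct lineages: entry costs $\tau$, persistence across slices is free,
re-emission into a sampled branch costs $\tau$.  This is the minimal
construction that lets transfers traverse lineages the species tree does not
contain; one channel suffices because unsampled lineages are
indistinguishable.  Duplication inside the channel is not modelled — under
non-negative costs a dead-side duplication is never strictly cheaper than
duplicating after re-emission, so no optimum is lost.  Origination of the
gene root is free on any branch in any slice (including a virtual stem above
the root), which is why origination carries no cost term.

Within a slice, transfer-loss couples same-clade values across branches; a
single-jump closure is exact because two consecutive jumps can always be
replaced by one direct jump of no greater cost.  Clades are processed in
order of increasing size, so all cross-references are to completed values.

With an integer-valued cost scheme the arithmetic is exact in doubles; cost
equality generally is tested at $10^{-9}$.

### Amalgamation

Given a posterior sample of gene trees, `build_ccp()` tabulates every
observed clade and split after discarding the first 25% of trees as burn-in
(the floor rule: `floor(0.25 N)` trees are dropped).  The same DP then ranges
over observed clades and their observed splits instead of the nodes of one
tree.  The parsimony search is *unweighted* — it uses the clade/split **set**
— while the observation frequencies are carried through for reporting.
Weighted amalgamation would mix posterior probability into a parsimony
objective with no principled exchange rate; keeping the search combinatorial
makes the amalgamated optimum provably no worse than the best sampled tree,
which is also what the test suite asserts.

### Tie-breaking and determinism

Among co-optimal histories the backtracking is deterministic: slice-bottom
moves (leaf, speciation, speciation-loss, null) are preferred to duplication,
duplication to transfer, transfer-loss last; receiver and survivor ties break
toward the lower species-branch index; origination ties toward the lower
branch index, then the younger slice.  We return one reproducible optimum and
make no claim of matching any particular representative (such as a symmetric
median) that other implementations may select among co-optima.

### Rooting

If the gene tree's rooting is not trusted, `reconcile(..., unrooted = TRUE)`
scores every edge of the unrooted topology as a root position and keeps the
cheapest, ties broken by edge index.  For amalgamated input the sampled trees
are taken as rooted.

## Certification strategy

Three independent routes check the engine:

1. an exhaustive oracle for instances with at most 4 gene and 4 species
   leaves that assigns every internal gene node an explicit event and
   location and charges lineage movement by all-pairs shortest paths in the
   (branch, slice) move graph.  Its `max_events` budget caps duplications
   plus transfers; losses are optimised exactly along paths, so with at most
   three internal gene nodes the cap of 4 is never binding and the
   enumeration covers all histories;
2. the classical LCA-mapping duplication–loss closed form, which the DP must
   match when $\tau = \infty$ (dating never constrains a transfer-free
   history);
3. the simulator's visible true history, which is feasible by construction,
   so the DP optimum can never exceed its cost.

## The synthetic-data generator

`simulate_gene_family()` runs a continuous-time forward process: along each
living gene lineage, exponential waiting times at the duplication, transfer
and loss rates (events per lineage per Ga); transfers land on a uniformly
chosen branch alive at the exact event time (sampled branches only, so every
true history is feasible for the DP — the dead channel is permitted, never
required, by synthetic truth); lineages split for free at speciation nodes.
Extinct subtrees are pruned and their event records collapsed: a speciation
with one extinct side becomes a single loss; a transfer whose donor side died
becomes a transfer-loss; a duplication with one surviving child is invisible.
What remains is exactly the event set a parsimony method could in principle
recover.

Default study conditions follow the analysis design: 20-leaf species trees
with a 4-Ga root for the lower-bound sweep, rates on a
$\{0, 0.1, 0.3\}\,\mathrm{Ga}^{-1}$ grid per event type, posterior-sample
surrogates of 50 trees perturbed by Poisson-many rooted NNI moves, and
abundance tables of $n = 139$ samples with phosphate drawn uniformly on
0–3.29 μM — the sample count and concentration range observed across the
Tara Oceans surface catalogue.  The simulation-based test sizes (50 oracle
instances, 200 lower-bound families, 27 sensitivity families, 20 amalgamation
samples, 2000 null regressions, 500 recovery replicates) were chosen as the
smallest rounds that make the binary properties decisive at desk scale.

What the generator deliberately does **not** emulate: sequence evolution and
alignment error (gene-tree uncertainty is injected directly as topology
perturbation), gene-tree estimation bias, extinct species lineages (the
species tree carries only extant, sampled taxa), replacement transfers, and
rate heterogeneity across branches.  Passing tests therefore certify the
*inference machinery* — not that real alignments will yield correct trees,
nor that parsimony costs are the truth of molecular evolution.

## Dating and chronology conventions

* Ages are Ga before present; larger is older, leaves sit at 0.
* Speciations are dated at the node where they occur.  In-branch events
  (duplications, losses, transfer receptions) are constrained only to a
  branch, so they are dated at the branch midpoint; a slice-midpoint mode is
  available behind a flag for finer dating but off by default, since the
  branch midpoint is the honest summary of what parsimony knows.
* Transfers are dated once, at the reception; the departure is the same
  event seen from the donor and would double-count.
* Events routed through the dead channel have no location on the sampled
  tree; they are tallied separately, never dated.
* Boundary ages map to the *younger* geological period (3.2 Ga is
  Mesoarchean, not Paleoarchean): deterministic and stated.
* Losses count toward first appearance by default — a loss implies the gene
  was already present — and can be excluded with a flag.
* Point ages only: posterior age uncertainty on species nodes is not
  propagated through the reconciliation.  Propagating it would require
  reconciling against many dated trees and summarising, which is beyond the
  scope of the parsimony engine.

## Homolog screening conventions

Internal-node bit scores are the mean over **descendant leaves**, not over
immediate children: the leaf mean is invariant to how the subtree is
resolved, whereas a children mean changes with arbitrary internal resolution.
The retained set is all leaves under the MRCA of the queries and the
threshold passers — monophyly is enforced by construction, and raising the
threshold can only shrink the set.  When a profile's trusted cutoff is not
supplied, the threshold defaults to the minimum query score, the most
conservative choice that still retains every query.  The e-value prefilter
(0.1) is documented as an upstream step on the score table, not re-applied.

## Regression conventions

Both model forms are first-class: linear (`abundance ~ phosphate`) and
log-linear (`log(abundance + pseudocount) ~ phosphate`), the latter being the
working interpretation of an "exponential" fit; the default pseudocount is
half the smallest non-zero abundance.  Slopes are tested two-sided via the
t statistic; residual degrees of freedom are $n - 2$.  A published analysis
of 139 samples reporting 129 degrees of freedom is not reproducible from
simple OLS ($139 - 2 = 137$); dropped samples are a plausible cause, so the
package reports its own honest $n - 2$ and logs how many samples were
dropped, rather than forcing a number.  Predictions are floored at zero
(abundances cannot be negative), and a constant response is reported as
slope 0 with p = 1 rather than as a numerical failure.

## Degenerate inputs and numerical choices

Polytomous species trees are rejected at parse time (the DP assumes binary).
Non-ultrametric branch lengths without explicit age annotations are rejected
naming the offending leaf pair.  Families whose simulation goes extinct are
returned as valid empty results; single-survivor families carry their one
leaf but no tree.  Zero-variance phosphate and all-zero abundances under the
log form abort with advice.  Cost comparisons use exact arithmetic on
integer schemes and a $10^{-9}$ tolerance otherwise; ages round-trip through
Newick at $10^{-9}$ Ga.

## Known limitations

Parsimony returns one optimal history; co-optima are not enumerated, and
event counts can be under-determined when costs trade off exactly.  First
appearance is a lower bound only — presence in unsampled lineages is
invisible by construction.  The dead channel models unsampled diversity as a
single undifferentiated pool, so it cannot date events that happened inside
it.  And the abundance regressions are correlational: they anchor
present-day ecology, not a causal reconstruction of ancient phosphate
concentrations.
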