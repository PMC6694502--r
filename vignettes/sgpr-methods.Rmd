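---
title: "Stoichiometric gene-protein-reaction rules: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric gene-protein-reaction rules: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgpr)
```

## The problem

Gene-protein-reaction (GPR) rules are the bridge between transcriptomics and
genome-scale metabolic models: a boolean expression per reaction in which
`and` joins the subunits of an enzyme complex and `or` joins isoenzymes.
Standard GPRs ignore how many copies of each transcript a functional
catalytic unit needs. When a complex uses two copies of the protein encoded
by gene `b` and one copy of the product of `a`, the classical rule `a and b`
treats both genes alike, while the stoichiometric rule (S-GPR) `a and 2*b`
divides the expression of `b` by two before aggregation. In near-isogenic
comparisons — two conditions whose transcriptomes differ at a fraction of a
percent of genes — that correction can flip a reaction across an integration
threshold and change which metabolite exchanges a model predicts to be
active.

This package implements the S-GPR formalism end to end: rule parsing,
construction from enzyme-composition tables, evaluation against expression
profiles, four constraint-based integration algorithms that consume the
resulting reaction scores, a qualitative evaluation of predicted exchanges
against measured metabolite consumption/production, and seeded toy-network
generators so the whole workflow can be exercised and property-tested at
desk scale.

## Rule semantics

A rule tree has gene leaves carrying a positive integer copy number and
`and`/`or` nodes with at least two children. During evaluation each leaf
takes the gene's expression value (GPR mode) or that value divided by the
copy number (S-GPR mode); `and` becomes `min` (a complex is limited by its
scarcest subunit) and `or` becomes `mean` or `max` (isoenzymes pool their
capacity). `and` binds tighter than `or`, parentheses override, and a
coefficient may only attach to a gene leaf — `2*(a and b)` is rejected so
that stripping coefficients is always a lossless, local operation and the
GPR is recoverable from the S-GPR by deleting the `n*` prefixes.

Two policies govern genes absent from a profile. The default, `skip`, lets
operators aggregate the defined children only, so sparse microarray coverage
does not silence a whole reaction; a rule with no defined leaf evaluates to
`NA` and the reaction is simply unscored. The alternative substitutes a
constant. Multiple probes per gene must be collapsed before profile
construction; `collapse_probes()` keeps the maximum, a conservative choice
toward detecting activity.

The choice of `mean` versus `max` for `or` is exposed in the configuration
(default `mean`) because no single convention dominates practice; every
algorithm here accepts either.

```{r}
cfg <- gpr_config(gpr_mode = "SGPR")
evaluate_gpr(parse_gpr("a and 2*b"), c(a = 4, b = 10), cfg)  # min(4, 10/2)
```

## Building rules from composition tables

Rule construction consumes a table with one row per (EC code, compartment,
catalytic unit, gene, copy number). Within an EC code each catalytic unit
becomes an `and` over its genes with their copy numbers, units join by `or`
(isoenzymes), and multiple EC codes on one reaction join by `and`, since
several codes on a single model reaction describe a lumped sequence of
activities that are all required. Rows whose compartment does not match the
reaction's — inferred from its metabolites, with transport reactions
matching any compartment they span — are excluded. Units and genes are
sorted lexicographically so the built rule is deterministic regardless of
table order. The table is deliberately a user-supplied artifact: it makes
rule construction reproducible and auditable, and published composition
resources can be converted into it offline. Conflicting stoichiometries for
the same complex must be reconciled before the table is written; the format
has no merge semantics.

## Model preprocessing

Models carry finite flux bounds (non-finite bounds are capped at ±1000, the
common convention in this model class), an objective reaction, optional
pathway labels and EC codes, and S-GPR strings. Preprocessing follows the
usual refinement sequence:

* **Exchange augmentation** adds, per measured metabolite, an irreversible
  uptake (written `∅ -> M`, so uptake flux is positive) and an irreversible
  secretion, skipping directions an existing exchange already covers.
* **Pruning** removes reactions whose flux-variability range is `[0, 0]`
  over the unconstrained steady-state polytope (blocked in any condition),
  turns reversible reactions with one infeasible direction irreversible, and
  drops metabolites left in no reaction, iterating to a fixed point. A
  blocked objective is an error, because the model can then never express
  its phenotype. Blockedness uses a numeric zero of `1e-9`, comfortably
  above solver noise and far below any meaningful flux at the ±1000 cap.
  Pruning preserves the flux polytope's projection onto the retained
  reactions, which the test suite checks by comparing FVA ranges before and
  after.

## The linear-programming layer

All methods reduce to linear or mixed-integer linear programs over the
steady-state polytope `S v = 0`, `lb ≤ v ≤ ub`. The package solves them with
an internal dense two-phase primal simplex using Bland's anti-cycling rule.
These polytopes are heavily degenerate (zero right-hand sides, redundant
rows), and Bland's rule trades speed for guaranteed, deterministic
termination — the right trade at the network sizes this package targets
(tens of reactions; the simplex was validated against an independent
interior-point/simplex implementation on random instances during
development). Binary problems are solved by a depth-first branch-and-bound
over the LP relaxation with a fixed branching order (first fractional
binary, zero branch first), so repeated runs are bit-identical. Absolute
fluxes are linearized by the standard split `v = p - q` with `p, q ≥ 0`.

Every method finishes with a parsimony tie-break: its own objective is fixed
at the optimum and total absolute flux is minimized before activity is
classified. LP optima over degenerate polytopes are rarely unique, and
without the tie-break the reported activity states would depend on pivot
order; with it they are reproducible across runs and platforms.

A reaction is **active** when `|v| ≥ 1e-6` (either direction), the
classification epsilon. The MILPs force flux through "on" reactions with a
separate, larger epsilon of 1.0 — the original iMAT convention — because
forcing only `1e-6` units of flux would label reactions active at values
indistinguishable from solver noise.

## The four integration algorithms

**GIMME** resolves an expression threshold (default: mean plus one standard
deviation of the defined reaction scores; percentile and absolute modes are
available), penalizes each below-threshold reaction by its shortfall times
its absolute flux, and minimizes the total penalty subject to the required
metabolic functionality (RMF): objective flux at least a fraction (default
0.9) of the flux-balance optimum. The optimal penalty is the inconsistency
score; zero means the RMF is attainable using only adequately expressed
reactions.

**iMAT** splits scored reactions at the 40th and 60th percentiles of the
defined-score distribution into low, moderate and high, then maximizes the
count of high reactions carrying at least the forcing epsilon (either
direction) plus low reactions carrying none. Quantiles use linear
interpolation; the upper cutoff is inclusive (`score ≥ q60` is high) so a
tied top group — the normal case in small or noiseless score sets — still
counts as highly expressed, while a completely flat score distribution
remains all-moderate and imposes nothing.

**The relative-expression method** (after Gonçalves and colleagues)
integrates treated/control ratios as continuous bounds. A parsimonious FBA
on the unmodified model gives control fluxes `v_c`; each scored reaction's
treated flux magnitude is then bounded by `r·|v_c|` in the control
direction, clipped to the original bounds, and a second parsimonious FBA
gives the treated fluxes. Down-regulation (`r < 1`) tightens the cap below
the control flux; up-regulation relaxes it above; a reaction the control
does not use stays unused. Lower bounds are never raised: an earlier
formulation that forced up-regulated reactions to at least their control
flux made any chain whose step ratios straddle 1 jointly infeasible under
realistic expression noise, so the cap-only rule was adopted. It reproduces
the expected desk cases — ratios of 1 return the control solution, halving
expression on a bottleneck halves its flux, doubling expression on a
reaction at capacity changes nothing — while guaranteeing that the rescaled
model is always feasible. For reactions with negative control flux the cap
applies to the magnitude with the sign preserved.

**MADE** turns per-gene log fold changes and p-values into per-reaction
desired transitions. The pair is propagated through the rule tree: `and`
keeps the child with the smallest log fold change (the limiting subunit),
`or` averages (mean mode) or keeps the largest (max mode); in S-GPR mode
leaf values are divided by copy numbers like any other leaf quantity, which
cannot flip a sign but can change which child an `and` selects. A reaction
with `p < 0.05` and positive (negative) fold change wants to switch on
(off); others want to stay the same. A MILP over two binary activity
vectors — each condition constrained to a steady-state pattern meeting its
RMF — maximizes the total weight `1 - p` of realized transitions matching
the desired ones. Reactions whose weight is zero impose no binary, so two
identical profiles reduce the problem to two independent parsimonious
flux minimizations and the two returned states are identical.

## Evaluation against measurements

Measured metabolites enter as replicate peak areas at two time points. A
two-sided Mann-Whitney test per metabolite (exact at desk scale — full
enumeration when ties are present, the classical exact distribution
otherwise; the normal approximation only above 25 replicates per group)
calls each metabolite consumed, produced (median direction) or unchanged at
`alpha = 0.05`; fewer than two replicates in a group makes it untestable. A
metabolite is predicted-active when any of its exchange reactions is
active. The 2×2 agreement table (predicted active/inactive × measured
exchange/no-exchange) yields the proportion of right predictions
`(a + d)/n` and a two-sided Fisher exact p-value. The S-GPR improvement is
reported primarily as the percentage-point difference of right proportions,
with the relative change attached as an attribute, since the two readings
differ and only the point difference is invariant to the baseline.

Pathway over-activation compares active-reaction counts per pathway between
conditions: the relative weight is the treated count over the control
count, a pathway with active reactions only in the treated condition is
flagged exclusive, and significance is a two-sample t-test on the
per-reaction 0/1 activity indicators. The t-test unit (per reaction, not
per method) is a documented choice; with a handful of reactions per pathway
it is indicative, not confirmatory.

## What the generators emulate — and what they do not

`generate_toy_model()` builds connected networks of linear chains off a hub
metabolite, with uptake and secretion exchanges, parallel branches,
isoenzyme (`or`) and multi-copy complex (`and` with copies ≥ 2) motifs, and
pathway labels; all reactions are irreversible with capacity 10, so every
generated model is feasible and prunes to itself. `generate_expression()`
draws log-normal replicates: genes of a planted-active reaction set sit a
configurable fold (default 4) above the rest, with log2-scale noise
(default 0.1) and five replicates per condition; the treated condition
flips a small fraction of genes (default 10%), and per-gene p-values and
fold changes come from the replicate draws. Measurements are peak areas
with multiplicative noise; consumed metabolites drop to 40% of baseline,
produced ones rise 2.5-fold — effect sizes a Mann-Whitney test resolves at
five replicates. Log-normal draws were chosen because intensity data are
positive and right-skewed.

The discriminating fixture is fully deterministic: a reaction gated by
`2*g1 and g2` with `g1 = 3, g2 = 2` scores 2 under GPR and 1.5 under S-GPR;
filler reactions scored 1.6–1.9 pin the iMAT percentile cutoffs inside
(1.5, 2), the GIMME absolute threshold is 1.75, and an alternative route to
the objective carries a penalty between the gated reaction's GPR penalty
(zero) and its S-GPR penalty. Under GPR both methods route flux through the
gated reaction and predict its byproduct's exchange active; under S-GPR
they do not; the bundled measurements show that metabolite unchanged, so
only the S-GPR call is right.

These generators emulate the *structure* of the study conditions — two
nearly identical conditions, subunit stoichiometry that matters at the
margin, qualitative exchange measurements — not the scale or biology of a
genome-scale human model: no reversible thermodynamics, no growth-coupled
biomass objective, no correlated noise between genes, no probe-level
artifacts. Passing tests therefore demonstrate correctness of the
machinery and the qualitative S-GPR phenomenon, not predictive performance
on real transcriptomes.

## Problem sizes and numerical choices

The test-suite and acceptance fixtures use networks of 8–16 reactions, 20
seeds for stochastic properties, exhaustive enumeration oracles up to 2^k
activity assignments, and every 2×2 Fisher table up to N = 40 — sizes at
which exact oracles are computable and the whole suite runs in well under a
minute. Key tolerances: blockedness and flux zeros at 1e-9, activity at
1e-6, MILP integrality at 1e-6, branch-and-bound pruning at 1e-7 (strict,
so the first-found incumbent wins ties deterministically).

## Known limitations

* Flux solutions of constraint-based models are not unique; the parsimony
  tie-break makes reported states reproducible, not biologically unique.
  Robustness analysis (which reactions are active in *every* optimum) is
  out of scope.
* The relative-expression method inherits its literature formulation's
  rigidity: a reaction unused in the control can never activate in the
  treated condition.
* Transcript levels proxy protein levels imperfectly; the formalism would
  benefit from proteomic input or translation-efficiency weighting, which
  the rule machinery would accept unchanged.
* The SBML reader/writer covers the Level 3 + fbc v2 subset this package
  emits (species, reactions, bounds, gene associations, objective, plus the
  `sgpr` annotation); it is not a general-purpose SBML implementation.
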