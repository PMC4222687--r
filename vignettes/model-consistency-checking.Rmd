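---
title: "Checking stoichiometric models for structural and constraint consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Checking stoichiometric models for structural and constraint consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcheck)
```

## The problem

A stoichiometric model represents a metabolic network by an m × n matrix
S: one row per internal metabolite, one column per reaction, negative
coefficients for reactants and positive for products.  Steady-state
analysis imposes S v = 0 on the flux vector v, together with per-reaction
bounds — by convention [-1000, 1000] for reversible and [0, 1000] for
irreversible reactions.  Exchange reactions connect the network to its
environment; external metabolites sit outside the modelled boundary and
are removed from S before any analysis.

Reconstructions assembled by hand or by automated pipelines routinely
contain defects that only surface during analysis: metabolites that can
only accumulate, reactions that can never run, reversibility annotations
contradicted by the surrounding network.  `fluxcheck` detects these
defects directly and reports them in a compact four-section summary.

## The conditions and how they are detected

**Connectivity (always checked).**  A *singly connected metabolite* (SCM)
has exactly one non-zero entry in its row of S.  A *dead-end metabolite*
(DEM) has non-zero row entries of one sign only: it is only produced or
only consumed, so at steady state every reaction touching it is forced
off.  Any SCM is trivially a DEM.  Rows that are entirely zero (orphan
metabolites) are counted separately and retained in the model — deleting
them would silently change the metabolite count.  The dead-end test is
evaluated literally on the signs of S, ignoring reversibility; this is
deliberate, as it makes counts comparable across tools and it is the
variant under which a metabolite consumed only by a biomass-style
reaction is *not* a dead end.  A reversibility-aware variant (a
reversible reaction both produces and consumes its participants) is
available behind `findDeadEnd(..., reversibilityAware = TRUE)`.

**Null-space basis (check type 0 or 2).**  An orthonormal basis B of the
kernel of S is computed from the singular value decomposition, with rank
decided by the standard threshold `max(m, n) * max(singular value) *
machine epsilon`.  A reaction whose row of B is entirely zero can carry
no steady-state flux whatsoever.  Two irreversible reactions whose rows
of B are proportional with matching zero patterns are *coupled* (CR):
their fluxes are in a fixed ratio in every steady state.  A negative
ratio (*reversibly coupled*, RCR) means the pair can only run with
opposite signs — impossible for irreversible reactions unless both are
zero, so RCR pairs indicate directionality errors.  RCR is a subset of
CR by construction.

**Flux variability analysis (check type 1 or 2).**  For each reaction,
the minimum and maximum of v_j subject to S v = 0 and the bounds are
computed: 2n linear programs.  A *zero-flux reaction* (ZFR) has both
optima equal to zero.  The FVA-detected blocked set is always a superset
of the basis-detected one, because the basis ignores directionality: two
irreversible reactions feeding the same dead end are blocked by FVA but
have non-zero basis rows.  A reversible reaction whose whole feasible
range lies on one side of zero has *unsatisfied reversibility* (UR) and
is annotated only-forward, only-backward, or zero.

## Parameters that matter

* **Flux bounds** (flux units; dimensionless here).  Defaults −1000/0 and
  1000 as above.  During checking, exchange-reaction bounds are reset to
  these wide defaults unless the user supplied bounds explicitly — the
  point of a consistency check is the network's structure, and a
  restrictive growth medium must not masquerade as a blocked pathway.
  User-supplied bounds always win.
* **Zero tolerance on FVA optima** (`tolFlux`, default 1e-9): well below
  the bound scale of 1000, above LP round-off.  The same value is used
  as the simplex pivot tolerance.
* **Coupling tolerances** (`tolRatio`, default 1e-6): basis rows are
  compared after normalising by a reference column fixed per candidate
  group, so the comparison is invariant to which orthonormal basis the
  decomposition happened to return; entries below `1e-9 * max|B|` count
  as zero.  These sit at double-precision SVD accuracy.
* **Stoichiometric zero threshold** (1e-12) when scanning S for
  connectivity: real coefficients are many orders of magnitude larger,
  so this only guards against parser float artifacts.

## Numerical choices

The linear programs are solved by a dense two-phase primal simplex
written for this package, using Bland's smallest-index rule throughout.
Bland's rule cannot cycle, so every LP terminates, and degenerate or
redundant equality systems — common in stoichiometric matrices, which
often contain linearly dependent mass-balance rows — are handled by
construction: dependent rows of S are dropped (via QR of the transpose)
before solving, and leftover artificial variables after phase 1 either
leave the basis or expose a redundant row, which is removed.  Each LP is
solved independently, so results do not depend on evaluation order.  A
dense tableau is entirely adequate at curation scale (hundreds of
reactions); for genome-scale FVA an industrial LP backend can be plugged
in behind the same solver contract (objective index, sense, S, bounds →
status, optimum).

The kernel basis uses LAPACK's SVD; kernel dimension 0 (full column
rank: every reaction blocked) and dimension n (no constraints) are both
handled.  Coupling detection groups rows by zero pattern before
comparing, so its cost is near-linear in n rather than quadratic.

## The synthetic generator

`fixtureNetwork()` provides five minimal, hand-checkable networks; the
worked truth for each (which metabolites are dead ends, which reactions
are blocked, every coupling ratio) ships alongside the model.
`randomPlanted()` builds a feasible irreversible backbone chain
(uptake → C1 → … → Ck → secretion), verifies by FVA that every backbone
reaction can carry flux, and grafts issue motifs onto distinct backbone
metabolites using fresh metabolite identifiers:

* a *dead-end branch* (one reaction into a new metabolite): plants one
  SCM, one DEM, one blocked reaction;
* a *blocked pair* (two two-step arms meeting at a new dead-end
  metabolite): plants one DEM, four blocked reactions and six coupled
  pairs, four of them reversibly coupled;
* a *one-way reversible cycle* (a reversible step out and an
  irreversible step back): plants exactly one unsatisfied-reversibility
  flag and nothing else.

Because motifs never share metabolites, the planted truth sets compose
without interference and *exact* recovery — not mere inclusion — is the
correct expectation, which is what the test suite asserts over 100
seeded networks.  Motif coefficients are drawn from {1, 2} so coupling
ratios other than ±1 occur.  The generator is deterministic for a fixed
seed and uses a private RNG stream.

What the generator does *not* emulate: realistic degree distributions,
compartments, cofactor hubs, or correlated motifs that share
metabolites.  Passing the recovery suite therefore demonstrates that
each detector is correct on its defining pattern and that the detectors
do not interfere, not that the package's counts on any particular
published reconstruction are reproduced; checking a real model remains
an empirical exercise (see `scripts/fetch_models.R`).

## Validation strategy

Three independent lines of evidence back the implementation, all in the
test suite:

1. hand-derived arithmetic on the fixtures (kernel vectors, FVA
   intervals, coupling ratios);
2. exact planted-truth recovery and the structural set relations
   (SCM ⊆ DEM ∪ orphans, RCR ⊆ CR, basis-zero ⊆ FVA-zero,
   reversible ∩ ZFR ⊆ UR) over seeded random networks;
3. an independent brute-force oracle: on networks with at most eight
   reactions, the extreme rays of the steady-state cone (double
   description on the cone with reversible reactions split) are
   enumerated exhaustively, and the FVA-blocked set must equal the set
   of reactions with zero net flux in every ray — 50 random instances.

Problem sizes were chosen to keep the whole suite fast: 100 planted
networks of 3–6 backbone metabolites for the property suite and 50
networks of up to 8 reactions for the ray oracle, which together run in
well under a minute.

## Degenerate inputs and edge cases

* Orphan metabolites are retained, warned about at load time, and never
  reported as dead ends.
* An SBML file whose species are all boundary-flagged is an error (no
  internal metabolites), as is an unknown identifier in an exchange or
  external list — silent skipping would hide typos.
* Duplicate species references within one SBML reaction are summed into
  a single coefficient (matrix semantics).
* A missing `reversible` attribute means reversible, following the SBML
  Level 2 default.
* The tabular reader accepts an optional leading identifier row/column,
  recognised only when the entire row/column is non-numeric, so a stray
  non-numeric cell inside the data still produces a located parse
  error.

## Known limitations

* The dead-end count, taken literally on signs, can disagree with
  curators' lists when a reversible reaction is a metabolite's only
  producer; the reversibility-aware flag exists for that reading.
* Coupling is reported for irreversible reaction pairs (the defining
  condition); `includeReversible = TRUE` extends it for exploration but
  those ratios do not carry the RCR interpretation.
* The dense simplex makes full genome-scale FVA slow; connectivity and
  basis checks remain fast at any scale.
* Full flux-coupling classification (directional/partial coupling) is
  out of scope; so are model repair and gap-filling — the report tells
  you what is inconsistent, not how to fix it.

## A complete run

```{r example}
net <- fixtureNetwork("net-combined")$model
report <- checkModel(net, checkType = 2)
cat(renderReport(report))
```

The JSON rendering (`renderJSON(report, net)`) carries the identifiers,
1-based indices, coupling ratios, UR direction annotations and the
bounds FVA ran under.
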