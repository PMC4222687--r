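# fluxcheck

Consistency checking for stoichiometric (constraint-based) models of
metabolism.

Genome-scale metabolic reconstructions are routinely shared and reused, but
there is no standard validation step before release: models in the public
domain frequently contain dead-end metabolites, reactions that can never
carry flux, or reversibility annotations the network structure contradicts.
Users typically discover these problems only when a downstream computation
(flux balance analysis, elementary-mode analysis) produces nonsense.
`fluxcheck` is for modellers who want to audit a model — their own before
release, or someone else's before reuse — and get a concise report of what
is structurally wrong.

## The checks

A network with *m* internal metabolites and *n* reactions is represented by
its stoichiometric matrix *S* (rows metabolites, columns reactions; negative
entries reactants, positive products).  At steady state the flux vector *v*
satisfies *S v = 0*.  Six conditions are checked:

| Condition | Meaning | Detected by |
|---|---|---|
| SCM | singly connected metabolite: row *i* of *S* has exactly one non-zero entry | sign/count scan of *S* |
| DEM | dead-end metabolite: all non-zero entries of row *i* share one sign | sign scan of *S* |
| ZFR | zero-flux (blocked) reaction: FVA gives v<sub>j</sub><sup>min</sup> = v<sub>j</sub><sup>max</sup> = 0 | flux variability analysis (2n LPs) |
| UR | unsatisfied reversibility: a reversible reaction with v<sub>j</sub><sup>max</sup> ≤ 0 or v<sub>j</sub><sup>min</sup> ≥ 0 | flux variability analysis |
| CR | coupled reactions: rows *b<sub>i\*</sub>*, *b<sub>j\*</sub>* of a kernel basis of *S* are proportional | null-space basis |
| RCR | reversibly coupled: as CR with a negative ratio | null-space basis |

A subset of blocked reactions (all-zero basis rows) is also found from the
kernel basis alone; the FVA-detected set is always a superset, because the
basis is oblivious to directionality bounds.  Flux bounds default to
[-1000, 1000] for reversible and [0, 1000] for irreversible reactions, with
exchange-reaction bounds widened to those defaults during checking so that
medium restrictions never masquerade as structural inconsistencies.

## Worked example

A three-reaction chain with a dangling branch: R1 imports A, R2 exports A,
R3 converts A into C — and nothing consumes C.

```r
library(fluxcheck)

net <- fixtureNetwork("net-b")$model
stoichiometry(net)
#>   R1 R2 R3
#> A  1 -1 -1
#> C  0  0  1

report <- checkModel(net, checkType = 2)
cat(renderReport(report))
#> Statistics:
#> 3 reactions
#> 0 reversible reactions
#> 2 exchange reactions
#> 2 metabolites
#>
#> Connectivity Checks:
#> 1 Singly connected metabolites (SCM)
#> 1 dead-end metabolites (DEM)
#>
#> Basis-based checks:
#> 2 coupled reactions (CR)
#> 0 reversibly coupled reactions (RCR)
#>
#> FVA-based checks:
#> 1 zero-flux reactions (ZFR)
#> 0 unsatisfied reversibility (UR)
```

C appears in exactly one reaction (the SCM line) and is only ever produced
(the DEM line), so R3 can never run at steady state (the ZFR line), while
the import/export pair R1, R2 must always carry equal flux (the CR line).
`renderJSON(report, net)` gives the same results with identifiers, indices,
coupling ratios and direction annotations.

Models are read from SBML (`readSBMLModel`) or from a tabular layout with a
trailing reversibility row (`readTabularModel`).  A command-line wrapper is
installed at `system.file("scripts", "check_model.R", package = "fluxcheck")`:

```sh
Rscript check_model.R --format tabular --check-type 2 model.tsv \
    --exchange exchange.txt --report report.txt --json results.json
```

It exits 0 for a clean model, 3 when any condition was flagged, 4 on input
errors.

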