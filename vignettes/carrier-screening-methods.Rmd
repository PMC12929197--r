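---
title: "Screening electron carriers for nitrogenase compatibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening electron carriers for nitrogenase compatibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nifscreen)
```

## Scope and model

Biological nitrogen fixation depends on small electron carriers —
ferredoxins carrying [2Fe-2S] or [4Fe-4S] clusters, and flavodoxins carrying
FMN — delivering electrons to the [4Fe-4S] cluster of the nitrogenase Fe
protein. Whether a given carrier can do this is, to a useful first
approximation, a question of two numbers: how close its redox cofactor gets
to the Fe-protein cluster in a docked encounter complex, and how fast a
single electron can tunnel across that gap given the two midpoint
potentials. `nifscreen` implements that screen: cofactor detection and
edge-to-edge distance measurement in PDB-format docking models, an
empirical tunneling rate law, interface salt-bridge analysis, and
threshold-based classification, plus a synthetic-complex generator that
stands in for a docking server during testing.

### The distance convention

The edge-to-edge distance *R* is the minimum Euclidean distance over all
pairs of designated *edge atoms*. For FeS clusters the edge atoms are the Fe
atoms; an optional policy (`edge_policy = "fe_and_s"`) adds the inorganic
sulfurs, default off, because the convention in this screening context is
Fe-to-Fe. FMN has no metal, and no community-standard "edge" subset; we take
the 14 atoms of the isoalloxazine ring system (N1, C2, N3, C4, C4A, N5, C5A,
C6–C9, C9A, N10, C10), i.e. the conjugated ring through which the electron
is carried, excluding the carbonyl oxygens, ring methyls and the
ribityl-phosphate tail. This was a genuinely open choice; the ring-only set
is the physically defensible one (the tail is saturated and takes no part in
redox chemistry) and it is exposed as the single place to change if a
different convention is wanted.

Carriers with two clusters (2[4Fe-4S] ferredoxins) contribute the cluster
*nearest* to the receptor cluster; ties break to the lower residue number so
results are reproducible. Hydrogens are ignored throughout — docking models
are heavy-atom — and alternate locations resolve to the first occurrence.

### The tunneling ruler

Rates come from the empirical single-step tunneling ruler. With driving
force $\Delta G^0 = (E_\mathrm{donor} - E_\mathrm{acceptor})/1000$ eV
(negative = downhill):

$$\log_{10} k_\mathrm{ex} = 13.0 - (1.2 - 0.8\rho)(R - 3.6)
  - 3.1\,(\Delta G^0 + \lambda)^2/\lambda \qquad (\Delta G^0 \le 0)$$

$$\log_{10} k_\mathrm{en} = 13.0 - (1.2 - 0.8\rho)(R - 3.6)
  - 3.1\,(-\Delta G^0 + \lambda)^2/\lambda - \Delta G^0/0.06
  \qquad (\Delta G^0 > 0)$$

Parameters, all exposed through `tunneling_params()`:

| parameter | default | units | meaning |
|---|---|---|---|
| `lambda_reorg` | 0.65 | eV | reorganization energy; the cellular-environment consensus value |
| `rho` | 0.76 | – | packing density of the intervening protein medium |
| `intercept` | 13.0 | log10 s⁻¹ | rate at van-der-Waals contact, optimal driving force |
| `contact_distance` | 3.6 | Å | van-der-Waals contact |
| `slope_a`, `slope_b` | 1.2, 0.8 | – | distance decay (1.2 − 0.8ρ) = 0.592 decades/Å at ρ = 0.76 |
| `franck_condon_coeff` | 3.1 | decades/eV | Marcus-type driving-force term |
| `thermal_factor` | 0.06 | eV/decade | uphill (Boltzmann) penalty |

The two branches are continuous at $\Delta G^0 = 0$ and linked by a
detailed-balance identity
($\log_{10} k_\mathrm{en}(\Delta G) = \log_{10} k_\mathrm{ex}(-\Delta G) -
\Delta G/0.06$); both are asserted to machine precision in the test suite.
Distances below contact are permitted with a warning (extrapolation), and
comparisons are done in log10 to avoid overflow.

The acceptor midpoint potential of the Fe protein defaults to **−415 mV**.
Reported values for ADP-bound Fe proteins span roughly −415 to −470 mV, and
−415 mV is the value under which the package's worked examples are
internally consistent: a −321 mV carrier crosses the 10⁶ s⁻¹ threshold at
exactly 10 Å on the 1 Å grid, and a −850 mV donor at 14.7 Å clears the same
threshold. It is a configuration argument everywhere it is consumed. One
caveat is deliberate: the grid-exact potential that first sustains
10⁶ s⁻¹ at 14.7 Å is −775 mV, less negative than the −850 mV figure often
quoted for this scenario; the package reports the grid-exact value and makes
no attempt to force the rounder number (the −850 mV donor does satisfy the
threshold, which is the claim that matters). Similarly, a −337 mV carrier at
13.7 Å evaluates to ~10^4.2 s⁻¹ under the default acceptor, not the
~10^5 s⁻¹ sometimes attached to that configuration; the discrepancy cannot
be resolved without knowing the acceptor value used there, so the computed
number stands.

For carriers with two distinct cluster potentials the higher (less negative)
one is used — the cluster that actually exchanges with the Fe protein.

### Thresholds, grids and classification

Threshold questions ("how far out can a carrier still sustain 10⁶ s⁻¹?",
"how low must its potential drop at fixed distance?") are answered on the
discrete grids the rate surface is modelled on — donor potentials −1000 to
−200 mV in 25 mV steps (33 values), distances 4 to 20 Å in 1 Å steps
(17 values) — rather than by continuous root finding. `build_rate_grid()`
materialises the full 33 × 17 surface; every cell equals an independent
scalar evaluation, a property the tests assert cell by cell.

`evaluate_carrier()` aggregates the top docking models by the arithmetic
mean of their distances and computes the rate **at the mean distance** (the
mean of per-model rates is also emitted; with a 0.592 decade/Å decay the two
differ for bimodal dockers, and both are reported rather than silently
choosing). Classification: `compatible` when mean R ≤ 10 Å (inclusive) *and*
log10 k ≥ 6; `incompatible` when neither holds; `marginal` when the two
criteria disagree. The `marginal` category is this package's own vocabulary —
distance/rate disagreement is informative (it flags low-potential carriers
docking far out, and close dockers with high potentials) and should not be
collapsed into either extreme.

### Salt bridges and hotspots

A salt bridge is called between side-chain charged-group heavy atoms — Arg
NE/NH1/NH2 and Lys NZ against Asp OD1/OD2 and Glu OE1/OE2, either polarity —
at a cutoff of **4.0 Å**, the conventional crystallographic criterion; the
screening literature this package serves plots per-pair distances without
fixing a cutoff, so the value is a parameter, not a derived constant.
Histidine is excluded (protonation ambiguous), as are backbone termini. One
bridge is reported per residue pair (closest atom pair recorded), and the
census is invariant under relabelling of the receptor homodimer's chains
except for the a/b annotation itself, which follows ascending chain-id
order. `hotspot_contacts()` projects the census onto the conserved
Fe-protein residues R101, R140, E112, E69 — per protomer, since a bridge to
R101 on chain a and one on chain b are different contacts.

### Distance–activity regression

`fit_distance_activity()` is ordinary least squares of activity on mean
distance with $r^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$, with two explicit
conventions: constant activity gives $r^2 = 0$ (not NaN), constant distance
is an error. Only the slope's sign is scientifically interpreted — activity
declines with distance — and that assertion is made on synthetic data with a
planted slope, not against any published coefficient, because published
activity values pair distances from one study with activities from another
and are not reproducible from structures alone.

## The synthetic-complex generator

`make_toy_complex()` builds the fixtures every pipeline stage is tested
against: a receptor surrogate (two short poly-alanine chains A and B, one
idealized cubane [4Fe-4S] cluster with 2.7 Å Fe–Fe edges) and a ligand chain
C carrying a [4Fe-4S], [2Fe-2S] or FMN cofactor. Placement is exact by
construction: the cofactors get seeded random orientations (rejecting the
measure-zero orientations without a clear unique extreme edge atom), and the
receptor's maximum-x edge atom and the ligand's minimum-x edge atom are
placed on the x axis exactly `target_R` apart. Every other cross pair is
then strictly longer by the separating-plane argument, and because the
anchor pair differs only in x, the requested distance survives rounding of
coordinates to the PDB's three decimals — measured R is within 10⁻³ Å of
target, which the generator verifies itself by re-measuring its own output
through `parse_structure()` → `split_receptor_ligand()` →
`nearest_ligand_cofactor()` before returning.

Salt bridges are planted as Glu/Asp–Lys/Arg residue pairs straddling the
interface plane at exactly `bridge_distance` (default 3.5 Å), spaced 12 Å
apart so bridges cannot cross-contaminate, with alternating polarity;
receptor-side residues reuse the hotspot numbering (112, 101, 69, 140)
first so hotspot reporting is exercised naturally. Decoy charged pairs go in
at `cutoff + 1.5` Å on the far side of the interface. Unsatisfiable specs
(bridge distance at or above the cutoff, or sterically impossible) error
before any output. Generation is a pure function of the spec: the same spec
yields byte-identical PDB text, and the caller's RNG stream is left
untouched.

`make_cohort()` plants the group structure the screen is meant to find:
per-role distance distributions with means 8.5 / 12 / 15.5 Å (nif-linked /
non-nif bacterial / plant) and sds 1.0 / 1.5 / 1.5 Å truncated below at
4 Å, midpoint potentials of −420 ± 40, −430 ± 60 and −380 ± 40 mV, three
models per carrier (emulating three independent docking runs), 3 / 1 / 0
planted salt bridges per role, and activities from
$\max(0,\ 150 - 8R + \varepsilon)$, $\varepsilon \sim N(0, 5)$. These are
*synthetic* values chosen once to mirror the qualitative separation seen in
docking screens of this system — shorter and saltier interfaces for
nif-linked carriers, long plain interfaces for plant ferredoxins — not
measurements. What passing tests show is therefore that the pipeline
recovers planted geometry and planted statistical structure exactly or
within sampling error; they cannot show that real docking poses are
predicted correctly, that real interfaces look like poly-alanine scaffolds
with grafted charges, or that the 10 Å / 10⁶ s⁻¹ thresholds are the right
ones for any particular organism.

## Numerical choices and problem sizes

- Coordinates are written and compared at the PDB's 3-decimal precision;
  distance contracts are honoured to 10⁻³ Å.
- Threshold solvers return `NA` (not an error) when no grid point qualifies.
- Nearest-cofactor ties break to the lower residue number; argmin ties in
  the distance matrix break to the first atom pair in record order.
- Quantiles in cohort summaries are interpolated order statistics (type 7),
  cross-checked in tests against a hand-written oracle.
- Test problem sizes: property checks use 1000 random (ΔG, R) draws; the
  generator round-trip runs seeds 1–20; slope recovery uses 50 replicate
  cohorts of 18 carriers fitted from their planted tables (structure
  emission off), with one full structural pass (generate → write → parse →
  measure → fit) on a 6-carrier cohort. These sizes give stable assertions
  while keeping the default suite fast to run.

## Interfaces

The package is function-first: `parse_structure()` / `write_structure()`,
`find_cofactors()` / `split_receptor_ligand()`, `edge_to_edge_distance()` /
`nearest_ligand_cofactor()` / `find_salt_bridges()` / `hotspot_contacts()`,
`tunneling_params()` / `driving_force()` / `log10_tunneling_rate()` /
`build_rate_grid()` and the threshold solvers, `evaluate_carrier()` /
`classify_cohort()` / `fit_distance_activity()` / `render_report()`, and the
generators. Results are classed S3 objects with print/plot/coef/predict
methods where those are natural. Carrier metadata travels as TSV
(`read_carriers()` / `write_carriers()`), reports as deterministic JSON
(`report_json()`) or a summary table (`report_table()`). These functions,
together with `scripts/acceptance.R`, are the package's command surface; no
separate shell front-end is shipped.

## Known limitations

- Docking poses are taken as given; the screen says nothing about pose
  quality, and real encounter complexes are dynamic ensembles of which a
  static distance is at best a proxy for whether transfer-competent
  orientations are sampled at all.
- The rate law is the single-step empirical ruler: no temperature
  dependence, no quantized nuclear motion, no multi-step hopping.
- mmCIF input is not supported; PDB-dialect text only.
- The salt-bridge census is geometric — no electrostatic continuum model,
  no hydrogen-bond or hydrophobic contact analysis.
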