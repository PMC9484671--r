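---
title: "Predicting amine reactivity toward NHS-ester reagents: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting amine reactivity toward NHS-ester reagents: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aminereact)
```

## The prediction problem

Activated-ester reagents (ATRP initiators, RAFT chain-transfer agents,
amine-reactive PEGs) acylate the primary amines of a protein: lysine
ε-amino groups and the α-amino group at each chain's N-terminus.
Which amines react, and how fast, is governed by structure: how
exposed the residue is to a reagent of that size, whether the amine is
protonated at the reaction pH, whether it is locked into an ordered
fold or sequestered in a hydrogen bond, and whether the local
electrostatic environment favours the reactive neutral form.
`aminereact` turns a tertiary structure (PDB) plus a per-atom charge
set (PQR, as produced by PDB2PQR) into a per-site classification:
fast-, slow-, or non-reacting.

The unit of prediction is the *amine site*: one ε site per lysine and
one α site per chain (its first standard residue), so an N-terminal
lysine carries two sites. All parameters are computed on the single
input conformation; no frame averaging or conformational sampling is
attempted.

## The five predictors

### Exposed surface area

The exposed surface area (ESA) of atom *i* is computed by Lee–Richards
slab integration: the atom sphere is inflated by the probe radius
$r_p$, cut into thin slices perpendicular to *z*, and the accessible
arc length of each slice circle is measured against all neighbouring
inflated spheres and integrated ($A_i = \sum_k f_k \, 2\pi R_i
\Delta z$, exact for an isolated sphere at any slice count). A
residue's ESA is the sum over its atoms; the site inherits its
residue's ESA.

Radii follow a compact ProtOr-style class table (carbonyl C 1.61 Å,
sp² C 1.76 Å, aliphatic C 1.88 Å, N 1.64 Å, O 1.42 Å, S 1.77 Å,
element fallback 1.80 Å). Hydrogens get radius 0 and neither carry
area nor occlude: areas are defined on crystallographic heavy atoms,
so a structure protonated in silico scores identically to the raw
crystal structure. Pseudo-atom fixtures may override radii per atom.

Numerical choices: 100 slices per atom by default (resolution floor
20); neighbour search over a uniform spatial grid with cell edge equal
to the largest inflated diameter; coincident atom centres are treated
as mutually occluding duplicates and flagged with a warning. A
Shrake–Rupley point-sampling variant (deterministic golden-spiral
lattice) is available as `sasa_algorithm = "shrake-rupley"`, and an
independent seeded Monte-Carlo estimator (`mc_atom_sasa()`) exists
purely as a test oracle.

The probe radius is the reagent-size dial: 4.2 Å corresponds to the
bromine-functionalised NHS-ester ATRP initiator, and larger values
(17–39.5 Å) approximate the hydrodynamic radii of PEGs.
`probe_scan()` recomputes everything per radius and reports class
flips. Two regimes are worth knowing about: on convex surfaces ESA
*grows* with $r_p$ (the accessibility surface is traced by the probe
centre), while crevice and interior sites *lose* area and can hit
exactly zero once the inflated neighbour spheres seal the opening —
that is the geometric mechanism behind bulky-reagent selectivity, and
the package's crevice fixtures reproduce it.

### Empirical pKa

The builtin backend is a deliberately transparent two-term heuristic:

$$\mathrm{p}K_a = \mathrm{p}K_\mathrm{model} + \Delta_\mathrm{burial} +
\Delta_\mathrm{charge}$$

with $\mathrm{p}K_\mathrm{model} = 10.5$ for ε-amines and $8.0$ for
α-amines; $\Delta_\mathrm{burial} = 0.01 \cdot \max(0, B - 280)$ where
*B* counts heavy atoms within 9 Å of the amine nitrogen (buried amines
shift up); and $\Delta_\mathrm{charge} = \sum \pm 0.5\,(1 - d/7)$ over
charged groups within 7 Å (Asp/Glu carboxylate oxygens raise, Arg CZ,
Lys NZ and chain termini lower). The site's own residue is excluded
from the charge sum — it is the titrating group, not its environment —
which also makes the isolated-amine limit exact: a lone lysine returns
exactly 10.5. The terms are additive by construction and reported per
site. All constants are exposed in `react_config()`.

This heuristic's only pipeline role is the pK\_a ≤ 10.3 branch of the
decision tree; it is not a general-purpose pK\_a predictor. For
higher-fidelity values a PROPKA-compatible predictor can be registered
(`pka_backend("external", fun)`); requesting an unregistered external
backend aborts the run before any scoring. pH does not enter the
predicted value — it is carried in the configuration (default 8.0) for
protocol fidelity and interpretation.

### Secondary structure

The 8-state assignment implements the classic Kabsch–Sander rules
natively rather than shelling out to a DSSP binary: backbone hydrogen
bonds scored by $E = 0.084 \cdot 332 \, (1/r_{ON} + 1/r_{CH} -
1/r_{OH} - 1/r_{CN})$ kcal/mol with a bond below −0.5 kcal/mol and at
most the two lowest-energy acceptors per donor; n-turns (3,4,5), the
minimal-helix rule (two consecutive turns) for G/H/I; bridge and
ladder detection for B/E; hydrogen-bonded turns T; bends S where the
CA direction changes by more than 70°. Amide hydrogens use the placed
hydrogen when present, otherwise the classic geometric estimate from
the preceding carbonyl. Conflicts resolve by the fixed priority
H > E > G > I > B > T > S > '-'. The three-state collapse is the
standard convention {H,G,I}→helix, {E,B}→strand, {T,S,'-'}→coil; the
classifier consumes only the three-state label, the report carries
both.

Sequence-adjacent donor/acceptor pairs are allowed (only self-bonds
are excluded), which matches the plain reading of the energy model;
such bonds cannot create turns or bridges, so assignments are
unaffected.

### Hydrogen-bond donor status

A site is a donor when its amine nitrogen donates at least one
hydrogen bond under Baker–Hubbard-style geometric criteria: covalent
D–H within 1.2 Å, donor–acceptor distance ≤ 3.0 Å and D–H–A angle
≥ 150° (both configurable; donors N/O with H, acceptors N/O/S,
intra-residue pairs excluded, salt bridges counted when the geometry
qualifies). The original Baker–Hubbard criterion bounds the H···A
distance; we adopt the donor–acceptor convention used by the common
trajectory-analysis implementations, which is the looser and more
widespread reading — the discrepancy only matters within ~0.3 Å of the
cutoff and both cutoffs are exposed. Acting solely as an acceptor does
not count: an H-bonded amine is sequestered only through its own N–H.

Because this step needs hydrogens, the pipeline places missing ones
geometrically: backbone amide H 1.01 Å from N anti to the preceding
carbonyl, three tetrahedral hydrogens on lysine NZ and on each
chain-terminal α-amino N, prolines skipped, existing hydrogens
untouched. This replaces a full optimisation-based protonation; since
donor status depends mainly on heavy-atom geometry at these cutoffs,
the fixed rule keeps results deterministic.

### Local Coulomb energy

The energy at the amine nitrogen is the full pairwise sum $E_i =
\sum_j k\, q_i q_j / (\varepsilon\, r_{ij})$ over the PQR charges with
$k = 332.0637$ kcal·Å/(mol·e²), no distance cutoff (the sum is cheap
at protein scale), and the amine's own residue excluded
(local-environment semantics, switchable). The dielectric defaults to
1 — bare Coulomb on the force-field charges — under which the
100 kcal/mol threshold sits in the intended magnitude regime; both are
configuration knobs because the source formulation leaves them open.
ε sites evaluate NZ; α sites evaluate the backbone N by analogy (only
NZ is anchored by the original description). $E_i > 100$ kcal/mol
(strictly) flags an area of low positive charge. Pairs closer than
0.5 Å are skipped with a warning.

## The decision tree

The published rule set this reconstructs was applied, not reprinted,
in its source; three branches are anchored to explicit statements
(ESA > 50 Å² required for reactivity, a pK\_a ≤ 10.3 branch point,
charge > 100 kcal/mol defining low positive charge) and the order and
direction of the remaining two are this package's design decision:
H-bond donation sequesters the amine (slow), and a low-positive-charge
environment accelerates reaction (fast). Evaluated in order:

1. ESA < 50 Å² → non-reacting;
2. pK\_a > 10.3 → slow-reacting;
3. helix → slow-reacting;
4. H-bond donor → slow-reacting;
5. low positive charge → fast-reacting, else slow-reacting.

Boundary semantics are fixed and tested: ESA exactly 50 is reactive,
pK\_a exactly 10.3 passes the branch, the charge flag is strictly
greater-than. The whole rule set is data (`classifier_rules()`,
serialisable with `write_rules()`/`read_rules()`), so a corrected tree
can be swapped in without code changes; each site's report records
every branch decision taken. The reconstruction is validated in the
test suite against all reported site classifications simultaneously
(buried, helical, pK\_a-branched and overexposed cases, including the
dimer/monomer class flip driven purely by the pK\_a branch).

## What the synthetic structures do and do not emulate

Everything the test suite scores is generated in code, seeded and
deterministic:

* *ideal helices* (φ = −57°, ψ = −47°, standard bond geometry, lysine
  side chains extended) exercise turn/helix detection and the whole
  pipeline;
* *β hairpins* built directly in hydrogen-bond space (paired residues
  carry mutually ideal N–H···O=C geometries) exercise bridge/ladder
  detection — the Kabsch–Sander rules consume only the bond pattern,
  so the connector's backbone realism is irrelevant;
* *sphere clusters* with explicit radii provide closed-form area
  oracles (isolated sphere, two-sphere cap formula, icosahedral-shell
  burial, cylindrical crevices);
* *charge systems* include the calibration pair (two unit charges at
  3.320637 Å give exactly 100 kcal/mol at ε = 1) and
  symmetric-cancellation layouts;
* *homodimers* (rigidly displaced copies) give exact count arithmetic:
  far copies double the reactive-site count, contact copies bury the
  interface.

These fixtures have known analytic answers, which is their point —
and their limitation. They do not emulate side-chain packing, rotamer
diversity, crystallographic disorder, force-field charge sets, or the
irregular surface topography of real proteins. Passing tests
therefore demonstrate the algorithms are implemented correctly, not
that predictions on any particular protein match experiment; the
regression test against crystallographic structures (1LYZ, 4CHA,
1GAL + PDB2PQR charge sets placed under `inst/extdata/rcsb/`) covers
the latter when those inputs are available. Problem sizes throughout
the suite were chosen for analytic transparency: clusters of 2–6
spheres, peptides of 4–12 residues, charge systems of up to 40 atoms;
the full pipeline runs on structures of a few hundred atoms, and the
implementation handles protein-scale inputs (10³–10⁴ atoms) in
seconds to minutes in pure R.

## Degenerate inputs and tie-breaks

Multi-model files use the first model only; alternate locations keep
the highest occupancy, ties preferring altloc "A" — one conformation
is scored, matching the single-conformation semantics of every
predictor. Waters are always removed; other hetero groups (including
modified residues such as MSE) are removed unless `keep_hetero`.
Chain-less PQR dialects are assigned chain "A" and re-labelled when
unambiguous. Reconciliation between PDB and PQR is by (chain, residue
number, insertion code, atom name); a mismatched hydrogen is
tolerated, a mismatched site nitrogen is fatal and names the site.
Chains without standard residues are skipped with a warning; an empty
post-cleaning structure is an error, as is an empty results table at
write time.

Two tolerance notes. Lee–Richards slab integration is exactly
translation-invariant but only rotation-invariant up to slice
discretisation (about 0.5 % at 100 slices, shrinking with resolution);
the suite asserts exact translation invariance and 1 % rotation
stability. And the human-readable CSV rounds to two decimals, so the
writer always emits a machine-precision long-format table alongside
it; determinism is asserted byte-wise on the latter.

## Known limitations

* The pK\_a heuristic is a branch-level surrogate, not a titration
  model: no coupled sites, no tautomers, no conformational relaxation.
* Charges are consumed, never derived: a PQR from PDB2PQR (or the
  package's formal-charge generator for synthetic structures) is
  required for the electrostatics stage.
* No mmCIF input, no biological-assembly expansion (select chains
  explicitly instead), no polar/apolar area decomposition, no
  Poisson–Boltzmann screening.
* The decision tree is a reconstruction; where its later branch order
  matters (sites failing several slow conditions at once), the
  rule-file override is the supported correction path.
* Reagent flexibility is not modelled: a PEG's effective size is
  collapsed into a single probe radius, which overstates exclusion
  from shallow depressions.
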