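---
title: "fragstitch: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fragstitch: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the tunable parameters with their defaults and rationale,
what the synthetic fixtures emulate (and do not), the numerical choices,
and the places where the design was genuinely open and a decision had to be
made. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The governing assumption

Everything downstream rests on one empirical observation from fragment
screening: elaborated ligands usually bind the way their parent fragments
did. `fragstitch` therefore never searches pose space. The candidate's
conformer is assembled *from the hits' own coordinates*, then relaxed only
locally and under restraints that keep it there. The snapshot binding
energy this produces is deliberately not a free energy — it is a
single-conformation bound-minus-unbound difference used as a sanity gate
(`ΔG_bind < 0`), and the pose-fidelity RMSD must always be read alongside
it.

Corollaries of the assumption:

* **no re-superposition, ever** — hits and protein are taken to share one
  crystal frame; RMSDs are computed in place. If your inputs are not
  pre-aligned the whole method is meaningless, so the package refuses to
  guess.
* **heavy atoms only** in mapping and RMSD. Crystallographic hits carry no
  hydrogens; hydrogens are synthesised geometrically only where needed
  (minimisation never sees them in the default united-atom engine;
  interaction profiling adds them for donor geometry).

## Ring collapse, merging and expansion

Positional atom overlap between two molecules is a one-to-one assignment
(minimum total distance; pairs beyond `map_threshold` forbidden) solved
exactly by a Jonker–Volgenant assignment. Maximum cardinality is
prioritised over total distance, which is what the 2 Å threshold semantics
require — but on aromatic rings it would happily return a *rotated*
ring-to-ring pairing (each atom matched to its neighbour's position,
~1.4 Å away). That is precisely the "overlap issue" the ring-collapse step
exists to prevent: overlap between ring systems is always computed on the
collapsed molecules, where a whole ring is one centroid pseudo-atom, and
placeholder pairs are expanded back to member-atom pairs afterwards.

On expansion, ring members stashed in several placeholders (fused systems)
re-unify exactly by identity; members from *different* source molecules
(merged placeholders) unify by minimum-distance assignment within
`map_threshold`, the earlier hit winning element, charge and coordinates.
Two merged rings can then come out three ways:

* **coincident** (the union has at most as many distinct atoms as the
  larger ring): a single perimeter ring is rebuilt by sorting members by
  angle in their best-fit plane. This is what turns a co-centred furan and
  benzene into one six-membered ring with one oxygen.
* **partially overlapping**: both bond sets are kept over the unified
  atoms, producing a fused, spiro or bridged system, with the later ring's
  bonds added only if valence allows; the rectifier repairs the rest.
* **not overlapping at all**: the placeholders never merged; linking
  handles connectivity.

**Where linking happens** was an open design point. The linker-length rule
(`n = round(d / 1.22 Å) − 1` atoms, first one a nitrogen unless
overridden) is stated on the distance between the two atoms actually being
joined. Linking on the collapsed graph would measure centroid-to-centroid
distances, inflating `d` by the two ring radii and inserting ~3 spurious
atoms between rings that should be directly bonded. `fragstitch` therefore
links *after* ring expansion, on real atoms: an atom is substitutable if it
is heavy, unprotected and has an implicit hydrogen to give up. The
`round(·) − 1` reading of the off-by-one rule means two atoms within
1.83 Å are bonded directly — consistent with a C–C bond forming across a
biphenyl-like 1.5 Å gap.

## Rectification

Stitching can produce impossible chemistry. The rectifier runs rule sweeps
to a fixpoint (at most 20):

1. an aromatic atom with two exocyclic heavy substituents dearomatises its
   ring (all ring bonds single, flags cleared) — the "geminal arene" rule;
2. overfull N/O gain a formal charge where one bond of slack suffices;
3. other overfull aliphatic atoms migrate their geometrically longest
   substituent to an adjacent atom with spare valence;
4. a carbon over valence four ("Texas carbon") loses its geometrically
   longest bond — geometry is the only information available to choose,
   and the longest bond is the most strained guess.

Valence accounting treats each aromatic bond as 1 plus one π unit for C/N
atoms carrying any aromatic bond, so benzene, furan, pyridine and
naphthalene junctions are all legal without kekulisation. The known
casualty is pyrrole-type N–H (counted pyridine-like, losing its implicit
H); none of the pipeline's decisions depend on that hydrogen. The
rectifier's output is guaranteed valence-legal or a typed
`RectificationFailure` — never a silent invalid molecule; bonds touching
protected warhead atoms are deleted only as a last resort.

## The MCS cascade

Placement maps the candidate's graph onto every hit with a strict maximum
common connected induced substructure search (element-, bond-order- and
ring-membership-exact); the largest match picks the *primary* hit (ties:
input order). Other hits are mapped under the constraint that wherever
their atoms positionally overlap the primary hit's mapped atoms (collapsed
overlap, as above), they must claim the same candidate atom. Laxer passes
then extend each map holding existing pairs fixed. The laxity ladder —
relax bond orders, then elements within a periodic group, then ring
membership — is this package's concretisation of "progressively laxer";
each step is config-exposed (`mcs_levels`). Cross-hit conflicts are
resolved by dropping up to `max_excluded` (default 3) pairs from the
smaller-coverage hit — the "red herring" mechanism that lets a stray
hydroxyl yield to a larger group occupying the same space. User-supplied
pairs are seeded into the search and never dropped: they genuinely
override, including chemically "wrong" swaps such as flipping the N and S
of an aminothiazole.

Novel atoms (no inferred equivalent) take coordinates from a generated
conformer superposed on the three mapped atoms nearest the patch — nearest
by graph distance to the patch's attachment atom, then by space, which was
the open interpretation point; anchoring at the attachment keeps the local
geometry right where the patch joins the core. The conformer comes from a
small deterministic distance-geometry embedder (ideal bond lengths from
covalent radii, 1–3 distances from ideal angles, regular-polygon ring
distance matrices, lower bounds elsewhere); one seeded conformer unless
the three-point fit residual exceeds 1 Å, then the best of ten.

## Minimisation engine

The default engine is intentionally a desk-scale, dependency-free
molecular-mechanics stand-in, not a published force field: harmonic bonds
(k = 300 kcal mol⁻¹ Å⁻², r₀ from covalent radii scaled by bond order),
harmonic angles (k = 40, θ₀ by hybridisation), 12-6 Lennard-Jones
nonbonded terms (ε = 0.1 kcal mol⁻¹, rmin from van der Waals radii) for
1-4+ and ligand–protein pairs, and a `k(1 + cos φ)` torsion penalty on
exocyclic secondary amides disfavouring the E/cis form. Mobile protein
atoms are softly restrained to the template (5 kcal mol⁻¹ Å⁻²) instead of
carrying a protein force field. The engine contract (coordinates +
restraints in, minimised coordinates + energies out) is pluggable, so a
physically serious engine can replace it without touching the pipeline.

Restraint tiers: heavy = 10 and moderate = 2 kcal mol⁻¹ Å⁻² — unspecified
upstream; chosen so that the heavy tier wins against typical bonded-term
forces (drift under 0.5 Å on the fixture suite, a tested property) while
the moderate tier lets rings relax. One deliberate deviation: the
restraints are **pure harmonic by default** (`restraint_flat_bottom = 0`)
rather than flat-bottomed with a 0.5 Å free zone. A free zone makes the
restraint-scale → ∞ limit test (minimised pose ≡ stitched conformer within
0.05 Å) unattainable by construction, because atoms drift force-free to
the bottom's edge; with harmonic restraints the limit holds and the
flat-bottom width remains available in the configuration for users who
want slack.

Pocket cycles: residues whose representative atom lies within
ligand length + 3 Å of the ligand centroid are mobile ("ligand length" =
maximum heavy-atom pairwise distance — the other open reading, radius of
gyration, underestimates elongated ligands). Each cycle minimises,
computes ΔG restraint-free (re-scored, not carried over from the
minimiser's objective), and halves the global restraint scale; the loop
stops at the first negative ΔG or after `max_min_cycles` (15), in which
case the result is *reported* with `acceptable = FALSE`, never raised.
The per-cycle scales are recorded in the result and are exactly
`2^−(k−1)`.

Covalent ligands: the dummy atom stands for the protein attachment atom
(nearest cysteine Sγ by default, overridable); it is excluded from
nonbonded terms and pinned by a heavy restraint, while a real bond term
(r₀ = 1.81 Å) joins the ligand's attachment carbon to the protein sulfur,
so the link survives minimisation and strained geometry shows up as
sulfur displacement. Warhead atoms (the dummy's neighbourhood up to the
first freely rotatable bond, operationalised as the contiguous π system —
an explicit atom list can be supplied instead) override the amide
restraint exemption: their coordinates come from the covalent hit and are
held at the heavy tier.

## Interaction profiling and ranking

The profiler is an in-repo geometric stand-in for external tools:
hydrogen bonds (D–A ≤ 3.5 Å, D–H–A ≥ 120° on the ligand side; protein
donors judged by distance only, since templates carry no hydrogens),
hydrophobic C–C contacts (≤ 4.0 Å, closest per residue), salt bridges
(≤ 4.5 Å between charged groups), π-stacking (ring-centroid ≤ 4.5 Å) and
halogen bonds (X···O ≤ 3.5 Å). All cutoffs are config-exposed. The rank
score is the documented linear form (the upstream description gives signs,
not magnitudes; the default weight vector is (1, 1, 1, 0.5, 1, 1)), lower
is better, with the per-term breakdown returned for customisation. The
acceptability filter implements *all hits used, RMSD < 1 Å, ΔG_bind < 0,
heavier than the largest hit*; the source material prints the ΔG sign
inconsistently in one table footnote, and the favourable-energy reading
(< 0) is implemented, matching the body text and the corresponding failure
category ("strain: ΔG > 0").

## What the synthetic fixtures establish

The fixture generator emulates: furan/benzene pairs at controlled centroid
separations (the distance-sweep), partially overlapping substructure pairs
(toluene/para-phenol on one ring), a ≤ 300-atom glycine-shell pocket with
a cavity, a covalent toy (cysteine + chloroacetamide-like hit, protein
file explicitly labelled *synthetic*), and seeded random drug-like
molecules (1–3 ring systems plus substituents, locally relaxed geometry).

They do **not** emulate: real protein folds or sidechain chemistry beyond
the residues the profiler keys on, crystallographic noise or partial
occupancy, tautomers and protonation states, or the conformational
strain statistics of real merges. A green suite therefore establishes the
*machinery* — exact round-trips, optimal assignment, schedule and
restraint semantics, typed failure taxonomy, covalent protection — not
predictive accuracy against crystal structures. The upstream worked
example that would establish the latter (a covalent placement against
deposited structures) needs downloaded crystallographic data and is
outside the offline test scope.

Fixture orientation is part of the stated world and chosen once: the sweep
furan has its oxygen pointing away from the benzene so that carbons face
the inter-ring gap. With that geometry the sweep passes through single
ring → two rings (directly bonded) → linked rings; the fused/spiro regime
collapses to near-coincident unification at the 2 Å threshold and is
instead exercised by a dedicated perpendicular-rings case.

## Numerical choices and degenerate inputs

* Assignment ties broken by ascending (left, right) index; all algorithms
  are deterministic at a fixed `seed`, and identical inputs give identical
  outputs byte-for-byte.
* The SSSR is built greedily from shortest cycles through each edge —
  adequate for drug-like ring systems; exotic cage polycycles are outside
  the intended domain.
* Empty positional maps are valid results; an empty MCS across all hits is
  a typed `MappingFailure`.
* 2D-only SDF records (no coordinate block, or all-zero coordinates) are
  rejected with the record index; altloc conflicts keep the
  highest-occupancy conformer with a warning (the upstream material is
  silent on multi-conformer hits).
* Distance-deferred hits are retried exactly once (the alternative,
  retry-until-stable, can live-lock on pathological geometries).
* L-BFGS-B with analytic gradients everywhere except the four-atom amide
  torsion term, which uses central differences (cheap, and avoids a
  fragile analytic dihedral gradient).

## Known limitations

* The energy model is qualitative; ΔG magnitudes are only comparable
  within a run, and ligand-efficiency values are on the engine's scale,
  not transferable to published LE statistics.
* Stereochemistry is ignored throughout (mapping, parsing, placement).
* Pyrrole-type N–H mis-counting, as above.
* The united-atom engine does not model explicit hydrogen bonding;
  favourable ΔG comes from dispersion-like terms only.
* Merging more than ~3 hits compounds the pairwise identity rules; the
  combinatorics of who-wins-identity are defined (earlier hit wins) but
  chemically crude.
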