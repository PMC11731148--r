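# fragstitch

Conserved-binding fragment merging, linking and constrained placement in R.

## The problem

Crystallographic fragment screening yields many small (< 250 Da) molecules
("hits") observed bound in the same protein pocket, all in one reference
frame. Designing a larger ligand from them means **merging** overlapping
hits, **linking** non-overlapping ones, or **placing** a designed candidate
so that it obeys the hits' observed atomic positions. Docking discards
exactly that positional information; `fragstitch` keeps it: the candidate's
conformer is *stitched together* from the hits' own coordinates and only
then minimised, locally and under strong hit-derived restraints.

The package is aimed at structure-based drug-design work at desk scale:
fragment-screening follow-up, merge triage, and regression-testable method
development.

## The method

**Combination** (merge/link) of positioned hits:

1. every ring is collapsed to a placeholder pseudo-atom at its centroid
   (atoms, bonds and attachments stashed inside) — this prevents spurious
   atom pairings between overlapping rings;
2. a one-to-one positional atom map (minimum total distance, pairs within
   2 Å) is taken between the collapsed molecules; hits are folded in
   pairwise in input order, a hit more than 5 Å from the growing merger
   being deferred once and then rejected (`DistanceFailure`);
3. atoms of the later hit absent from the merger are absorbed with their
   coordinates; rings are expanded back (overlapping ring members unify,
   the earlier hit winning identity);
4. if the result is disconnected, the two closest substitutable atoms are
   joined by an alkyl chain of `round(d / 1.22 Å) − 1` atoms, the first a
   nitrogen by default;
5. the chemistry is *rectified*: geminal-substituted arenes are
   dearomatised, overfull N/O gain a formal charge or migrate a
   substituent, pentavalent "Texas" carbons lose their geometrically
   longest bond.

**Placement** maps an arbitrary candidate (SMILES) onto the hits with a
multistep MCS cascade — a strict search (element-, bond-order- and
ring-exact) seeds the core from the largest-coverage hit, progressively
laxer passes extend it, constrained by the hits' mutual positional overlap,
with up to 3 blocking atoms excluded automatically — then borrows the
mapped atoms' coordinates and embeds only the novel patches from a seeded
conformer superposed on the three nearest mapped atoms.

**Minimisation** is two-stage: a pre-minimisation against a frozen protein
cutout, then in-pocket cycles in which nearby residues move and the
restraint weights are *halved each cycle until the snapshot binding energy*
`ΔG_bind = E(bound) − E(unbound)` *is negative* (a single-snapshot
difference, not a free energy). Mapped exocyclic atoms are restrained
heavily (10 kcal mol⁻¹ Å⁻²), ring atoms moderately (2), amides/ureas/esters
and novel atoms not at all, with an extra torsion penalty against E/cis
secondary amides.

**Scoring**: a geometric interaction profiler (hydrogen bonds, hydrophobic
contacts, salt bridges, π-stacking, halogen bonds), a linear multiterm rank
score penalising lost interactions, novel atoms, ΔG and rotatable bonds and
favouring conserved atoms and interactions, ligand efficiency
`LE = −ΔG/HAC`, and the acceptability filter: *all hits used, RMSD to hits
< 1 Å, ΔG_bind < 0, more heavy atoms than the largest hit*.

Covalent ligands are handled through a dummy atom (`*` in SMILES, `R` in
SDF) marking the protein attachment; the warhead neighbourhood is protected
from all merging edits and the C–S link to the nearest cysteine persists
through minimisation.

## Worked example

```r
library(fragstitch)

# two synthetic hits sharing a benzene ring: toluene and para-phenol
hits   <- make_overlap_pair()
pocket <- make_toy_pocket()

# combine them, minimise in the pocket, score
s <- combine_hits(hits, fs_config())
r <- build_restraints(s, fs_config())
s$mol <- premin_frozen_neighbourhood(s, r, pocket)
p <- pocket_min_cycles(s, r, pocket, fs_config(), hits = hits)
p
#> <minimized_placement 'toluene+phenol': dG_bind=-2.50, rmsd_vs_hits=0.04 A,
#>  1 cycle(s), acceptable=TRUE>

# place the designed merger 4-methylphenol against the same hits
pl <- place_candidate("Cc1ccc(O)cc1", hits, pocket, fs_config())
pl$rmsd_vs_hits   # 0.0378 -- the pose deviates < 0.04 A from the parent hits
pl$dG_bind        # -2.50  -- favourable snapshot binding energy
acceptability(pl, hits)$acceptable   # TRUE
```

`dG_bind` is the restraint-free ligand–protein interaction energy of the
final snapshot (negative = favourable); `rmsd_vs_hits` is the combined
heavy-atom RMSD of hit-derived atoms against their parent coordinates in
the shared crystal frame (no re-superposition — the method's fidelity
measure).

From the command line:

```sh
Rscript -e 'fragstitch::fragstitch_cli()' fixtures --kind ring_pair_sweep \
    --sep 0,2,4,6,8 --seed 42 --out fx
Rscript -e 'fragstitch::fragstitch_cli()' combine --hits fx/ring_pair_sep0.sdf \
    --out out
Rscript -e 'fragstitch::fragstitch_cli()' place --smiles cands.smi \
    --hits hits.sdf --template prot.pdb --out out
```

Every run writes a JSON log (config echo, seed, timings, failure taxonomy);
exit codes distinguish distance (3), rectification (4), minimisation (5)
and mapping (6) failures.

## Limitations

See the methods vignette (`vignettes/fragstitch-methods.Rmd`) for the model
assumptions, parameter rationale, what the synthetic fixtures do and do not
emulate, and the full list of numerical choices.
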