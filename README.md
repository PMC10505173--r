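# rnaforge

Restraint-driven folding of RNA tertiary structure on a coarse-grained,
rigid-frame representation.

## The problem

Predicting where an RNA chain sits in three dimensions is commonly split
into two learned products: direct per-residue placements (an ensemble of
coordinate predictors) and probabilistic restraints over inter-residue
geometry (binned distances and long-range dihedrals). Turning those
products into an actual structure requires a folding engine: a
differentiable energy that respects the chain's chirality, and an
optimizer over residue placements. `rnaforge` implements that engine
end to end for users who study RNA structure prediction methods —
people who want to dissect, stress-test or extend the folding stage
without training networks for weeks.

Each nucleotide is three beads (P, C4', glycosidic N — N9 for purines,
N1 for pyrimidines) placed by a rigid frame `T_i = (R_i, t_i)`. Two
energies act on the frames:

* the **frame-anchored term** `E_e2e`: summed over reference
  predictions, residue frames `i` and bead atoms `j`,
  `min(d_cut, sqrt(||T_i^-1(x_j) - T_i'^-1(x_j')||^2 + eps))` with
  `d_cut = 30` Å, `eps = 1e-3` — invariant to rigid motion, sensitive
  to reflection;
* the **geometry term** `E_geo`: per residue pair, cubic-spline curves
  over negative log-probabilities of binned P–P / C4'–C4' / N–N
  distances (56/44/32 bins over [2,30]/[2,24]/[2,18] Å) and three
  long-range dihedrals (36 bins), distance curves normalized by a
  reference bin, dihedral curves periodic and weighted 0.5.

The hybrid energy `E_DL = E_e2e + E_geo` is minimized by multi-start
L-BFGS over per-residue exponential-map rotations and translations,
with analytic gradients; the lowest-energy trajectory wins. The package
also ships a configurable-scale implementation of the two-track
transformer / invariant-point-attention network the restraints come
from (trainable at toy scale on a CPU, on a hand-written reverse-mode
tape), full-atom reconstruction from bead models, the standard RNA
model-quality metrics (P-RMSD, TM-score with RNA `d0`, INF, DI,
handedness, a clash estimate), and an oracle module that manufactures
restraints from reference structures so everything is exercisable
without trained weights.

## Worked example

Fold a 20-nt hairpin from oracle restraints (sharp geometry tensors +
six noisy coordinate predictions derived from the reference), then
score the result:

```r
library(rnaforge)

ref <- make_reference("hairpin", stem = 8, loop = 4, seed = 1)
paste(ref$sequence, collapse = "")         # "GCCUGUUCAAAAGAACAGGC"
render_dot_bracket(ref$ss)                 # "((((((((....))))))))"

geo <- oracle_geometry(ref$beads, oracle_config(temperature = 0.5))
e2e <- oracle_e2e(ref$beads, oracle_config(replicas = 6, seed = 1))
fit <- fold_rna(ref$sequence, e2e_pred = e2e, geo = geo,
                cfg = folding_config(max_iter = 250))
fit
#> <folding_result> 6 trajectories, selected # 2 with energy 9938.66
#> trajectory energies: 9941.38 9938.66 9945.79 9954.71 9956.26 9941.41

full <- fast_fixes(reconstruct_full_atom(fit$beads, ref$sequence, ref$ss))
score_model(fit$beads, ref$beads, ss = ref$ss,
            ref_interactions = interaction_set(wc = ref$ss$pair_table, L = 20),
            pred_interactions = detect_wc_pairs(full),
            model_fa = full)
#>   rmsd_p tm_score inf_wc inf_nwc inf_stack inf_all    di handedness clash_per_1000
#> 1  0.224     0.89      1      NA        NA       1 0.224      0.923            387
```

Reading the numbers: the six trajectories end at closely spaced
energies and the best one reproduces the reference to 0.22 Å P-RMSD
(TM-score 0.89 — the RNA `d0` for L = 20 is only 0.6 Å, so even
sub-Ångström models do not reach 1). All eight Watson–Crick pairs are
recovered geometrically from the rebuilt full-atom model (INF_wc = 1;
the non-WC and stacking categories have empty references here, so they
are not applicable), DI equals RMSD at INF 1, and 92% of paired
residues have pseudotorsions closer to the target than to its mirror.
The clash figure illustrates the division of labor in reconstruction:
with bead atoms frozen, small bead-level deviations leave residual
heavy-atom contacts that the fast local fixes cannot fully relax —
removing them is exactly what the external-minimizer hook
(`refinement_hook()`) is for.

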