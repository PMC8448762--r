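---
title: "Hierarchical TLS disorder decomposition: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical TLS disorder decomposition: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A refined structure's atomic displacement parameters are treated as the sum
of independent Gaussian disorder contributions at different length scales:

$$\mathbf{U}^{\mathrm{total}}_a \;=\; \sum_{l=1}^{n_\mathrm{tls}} \mathbf{U}^{\mathrm{tls}}_{l,a} \;+\; \mathbf{U}^{\mathrm{atomic}}_a .$$

Each TLS level partitions (a subset of) the atoms into disjoint rigid
groups. A group's contribution to atom $a$ follows the standard small-angle
rigid-body closed form
$\mathbf{U} = T + A_a L A_a^\top + A_a S + S^\top A_a^\top$, where $A_a$ is
the antisymmetric matrix of the lever arm $r_a - \mathrm{origin}$, $T$ (Å²)
and $L$ (rad²) are the translation and libration covariances and $S$
(Å·rad) the screw cross-covariance $\mathrm{Cov}(\theta, t)$. Matrices are
stored in normalized form $\mathbf{U}_g = A_g\,\hat{\mathbf{U}}_g$ with
$\frac{1}{n_g}\sum_{a\in g}\tfrac13\mathrm{Tr}(\hat{\mathbf U}_{g,a}) = 1$,
so the scalar amplitude $A_g$ is the group's mean-square displacement and
$8\pi^2 A_g$ its mean B-factor contribution. The atomic level is normalized
the same way per atom ($A_a = \tfrac13\mathrm{Tr}(\mathbf U_a)$).

We use the exact $8\pi^2 = 78.9568\ldots$ everywhere for B conversions (a
rounded "72" that sometimes circulates is not used).

Assumptions worth stating plainly: disorder sources are uncorrelated (so
they add); rigid-body motions are small-angle (the TLS closed form is the
linearized covariance); and a "level" expresses *compatibility* of atom
disorder with a shared rigid motion, not proven correlated motion.

## The fitting algorithm

All optimization minimizes the weighted least-squares target
$\sum_a \omega_a (\mathbf U^{\mathrm{target}} - \mathbf U^{\mathrm{model}})_a^2$,
with $\omega_a \propto 1/(\tfrac13\mathrm{Tr}\,\mathbf U^{\mathrm{input}}_a)$
normalized to sum to 1; large-B atoms thus pull less on the large-scale
levels. The tensor contraction is the squared Frobenius norm of the full
symmetric 3×3 difference (off-diagonal elements counted twice) — the
standard rotation-invariant choice. For atoms carrying only an isotropic B
the per-atom term is $(\tfrac13\mathrm{Tr}\,\Delta\mathbf U)^2$.

Per **macrocycle**, elastic-net weights are fixed at
$\Omega^\alpha = \gamma\,\gamma_0\,\delta^{m-1}$ (lasso) and
$\Omega^\beta = (1-\gamma)\,\gamma_0\,\delta^{m-1}$ (ridge). **Microcycles**
then iterate until amplitudes stop changing:

1. *TLS matrix step*, largest scale first. For each group with non-zero
   amplitude, the 20 free normalized elements (6 T, 6 L, 8 S with
   $\mathrm{Tr}\,S = 0$) are refined by Nelder–Mead against the level target
   $\mathbf U^{\mathrm{input}} - \sum_{l\neq k}\mathbf U^{\mathrm{echt}}_l$,
   at fixed amplitude. Candidates failing the validity screen are rejected
   via a graded penalty. After the search the matrices are renormalized to
   unit mean trace (amplitude rescaled inversely, per-atom products
   unchanged).
2. *Atomic step*: the PSD-constrained minimizer of the atomic-level target
   is the eigenvalue-clipping projection (exact, no search needed); shapes
   are updated per atom only when this does not increase the residual at the
   current amplitude.
3. *Amplitude step*: all group and atomic amplitudes are optimized jointly
   (the data couple them through the shared residual) by L-BFGS-B with
   analytic gradients, bounded below by zero, warm-started at the current
   amplitudes.

Convergence is declared when the largest amplitude change stays below
`db_cutoff` (0.1 Å² in B units) for `max(2, ceiling(stable_fraction · m))`
consecutive macrocycles, or when the optional RMSD cutoff
$\sqrt{\mathrm{mean}_a\,\lVert\Delta\mathbf U\rVert_F^2/3}$ is reached.

### Why the objective is provably non-increasing

Two details make the penalized objective monotone across microcycles, which
the tests assert on every fit:

* The simplex objective includes the elastic-net cost of the *renormalized*
  amplitude $A_g \cdot s(x)$ (where $s(x)$ is the candidate's mean trace),
  so the mandatory renormalization cannot raise the objective after the
  search.
* The atomic step is amplitude-preserving and accepted per atom only when
  not worse; amplitudes are owned entirely by the joint elastic-net step,
  which never accepts a worse point than its warm start.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `gamma` | 0.9 | — | lasso/ridge mixing; 1 = pure lasso (sparsest) |
| `delta` | 0.8 | — | per-macrocycle penalty decay |
| `omega0` | `"auto"` | Å⁻²-scale | initial total penalty weight |
| `kappa` | 5 | — | auto-scaling multiplier for `omega0` |
| `db_cutoff` | 0.1 | Å² (B) | amplitude-stability threshold |
| `stable_fraction` | 0.25 | — | fraction of cycles amplitudes must hold |
| `rmsd_cutoff` | none | Å² | optional early stop on model-input RMSD |
| `eps_psd` | 1e-6 | Å² | eigenvalue tolerance for PSD tests |
| `simplex_step` | 0.01 | — | initial simplex increment per element |

**Auto-scaling of the initial penalty.** An amplitude leaves zero exactly
when the residual gradient at $A=0$ exceeds $\Omega^\alpha$. For a
full-coverage group whose shape matches the data, that gradient is
$2\sum_a \omega_a \langle \mathbf U_a, \hat{\mathbf U}_a\rangle \approx
2 f \bar c$, where $\bar c$ is the weighted mean amplitude
($\sum_a \omega_a \tfrac13\mathrm{Tr}\,\mathbf U_a$) and the metric factor
$f$ is 3 for anisotropic atoms (Frobenius metric) and 1 for isotropic ones
(trace metric). We therefore set
$\gamma_0 = \kappa\,\bar c\,\bar f/3$ with $\kappa = 5$: the initial lasso
weight $0.9\,\kappa = 4.5$ sits *below* the first level's activation
threshold ($\approx 6$ in these units for anisotropic input) but far above
that of any group covering a minority of atoms, so macrocycle 1 admits the
largest-scale level only — the intended "all disorder at the bottom first"
schedule. A multiplier of 10, by contrast, suppresses *everything* for the
first two or three macrocycles (and, without the metric factor, isotropic
input converges on an empty model); both failure modes were the reason this
calibration is derived rather than guessed.

## Numerical and structural choices where the design was open

* **Group origin**: centroid of the selection, fixed during optimization.
  The centroid minimizes T/L coupling and is the common crystallographic
  choice.
* **S trace**: 8 free elements with $S_{33} = -(S_{11}+S_{22})$; the trace
  of S is not determined by the ADPs.
* **Simplex frame**: the initial simplex increments each element in the
  eigenframe of the current L (lab frame when L = 0, where the eigenframe is
  undefined).
* **Validity screen** (in place of the full published TLS-decomposition
  protocol, which is out of scope): T PSD, L PSD, the columns of S in the
  range of L, and the conditional translation covariance
  $T - S^\top L^{+} S$ PSD, all within `eps_psd`. This is exactly the
  condition for the joint Gaussian over (rotation, translation) to exist,
  and is the same factorization the ensemble sampler uses — so "valid"
  means "samplable".
* **Level order within a microcycle**: largest scale first, atomic last.
* **Zero-amplitude groups** are skipped in the matrix step (their objective
  is flat); they re-enter when the amplitude step lifts them above zero.
* **Coil residues at the secondary-structure level** become singleton
  per-residue groups, keeping the level's coverage complete; the elastic net
  zeroes them when unneeded.
* **Secondary structure** is a built-in two-class Kabsch–Sander rule
  (electrostatic H-bond energy, −0.5 kcal/mol cutoff; helices from two
  consecutive i→i+4 turns, strands from bridge ladders of length ≥ 2;
  amide H reconstructed geometrically; no inter-chain bridges). This avoids
  an external DSSP binary; for grouping purposes the two-class assignment
  suffices.
* **Ties / determinism**: the fit has no stochastic component — simplex and
  L-BFGS-B are deterministic from their warm starts — so identical inputs
  and configs give identical traces. In isotropic mode, TLS anisotropy is
  not constrained by the data (parameter sets with equal per-atom traces fit
  equally); the deterministic iteration picks one representative.
* **Degenerate inputs**: atoms with zero ADP trace make the weights
  undefined and are a hard error; groups whose matrices produce zero mean
  trace cannot be normalized and keep amplitude 0; non-PSD *targets* are
  allowed (they are fitting targets, not physical ADPs).
* **Occupancies** are read and written but do not enter the optimization.

## What the synthetic generator emulates — and what it does not

`make_peptide()` builds chains with standard backbone bond geometry from
fixed (φ, ψ) torsions, Cβ atoms and small idealized sidechains;
`make_ground_truth()` composes per-atom ADPs additively from chosen TLS
groups (any T/L/S shapes that pass the validity screen) plus optional
truncated-Gaussian isotropic noise, guaranteeing PSD totals. Defaults used
in the tests mirror the validation fixtures: a chain level of ~10 Å², a
two-level variant of 8 Å² + one 20 Å² hot residue, noise at 0–1 Å².

It does **not** emulate: realistic rotamers or packing, correlated noise,
refinement artefacts (B-restraint over-smoothing, TLS-refinement bias),
occupancy/altloc complexity, or experimental-data coupling. A green
recovery test therefore establishes that the optimizer solves the stated
inverse problem — additive hierarchical TLS disorder with independent
noise — not that any particular refined structure decomposes
meaningfully; for real data the caveats about input-model quality apply.

`sample_rigid_ensemble()` is the independent oracle for the TLS closed
form: it draws (θ, t) from the joint Gaussian (θ ~ N(0, L), then
t | θ ~ N(S^⊤L⁺θ, T − S^⊤L⁺S)), applies δ = t + θ×(r − origin), and
compares empirical covariances to `tls_uij()`. Element-wise agreement is
asserted at 5% relative to `max(|element|, Tr(U)/6)`: the sampling standard
error of a covariance element scales with the tensor's overall magnitude,
so a literal per-element relative error is unattainable for near-zero
elements at 10⁵ samples, and small elements are judged against the tensor's
own scale instead.

## Known limitations

* No symmetry constraints across chains and no inter-residue smoothness
  restraints; symmetry-related copies can come out slightly different
  (a small decay factor makes this worse).
* Isotropic-mode anisotropy is a modelling choice, not a data constraint.
* The PDB/mmCIF codecs are minimal (ATOM/HETATM/ANISOU/REMARK 3 TLS;
  atom_site/atom_site_anisotrop); exotic records are ignored.
* Level configs are JSON only.
* Runtime scales with (number of active groups) × (atoms per group) per
  microcycle; the implementation targets analysis-scale use, not refinement.
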