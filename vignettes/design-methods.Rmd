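---
title: "Hallucination-based design of soluble membrane-protein analogues: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hallucination-based design of soluble membrane-protein analogues: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solufold)
```

# The design problem

Integral membrane proteins carry fold topologies — four-helix claudin
bundles, six-helix rhomboid proteases, seven-helix GPCRs — that are largely
absent from the soluble proteome. A soluble analogue keeps the fold while
replacing the lipid-facing hydrophobic surface with a hydrophilic,
solution-stable one. `solufold` implements the full computational route to
such analogues at desk scale:

1. **Hallucination.** A position-specific scoring matrix (PSSM, N x 20
   logits over `ACDEFGHIKLMNPQRSTVWY`) is optimized by gradient descent so
   that a structure-predictor ensemble folds the decoded sequence into a
   given target structure with high confidence.
2. **Inverse folding.** Converged backbones are handed to a sequence sampler
   (the role a fixed-backbone inverse-folding network plays), with a
   hydrophilic sampling bias, fixed functional positions, optional backbone
   noise, and a hard cysteine mask.
3. **Filtering.** Every candidate is re-predicted and gated on structural
   similarity to the target (TM-score), prediction confidence (pLDDT) and
   sequence novelty (BLAST best e-value).
4. **Functionalization.** Native epitopes are transplanted onto passing
   scaffolds by residue-level sequence grafting, and chimeras are screened
   by re-prediction.

Real neural predictors are deliberately out of scope: the package defines
their interface contract (`predictor_contract()`) and ships a deterministic
**toy folder** plus an ideal-geometry **fixture generator** so that every
stage, test and example runs in seconds with no downloads, no GPU and no
network weights.

# The composite loss

Designs are optimized under

$$\mathrm{loss} = W_{\mathrm{FAPE}} L_{\mathrm{FAPE}}
 + W_{\mathrm{dist}} L_{\mathrm{dist}}
 + W_{\mathrm{pLDDT}} L_{\mathrm{pLDDT}}
 + W_{\mathrm{pTM}} L_{\mathrm{pTM}}$$

* $L_{\mathrm{FAPE}}$ — mean Euclidean distance between predicted and target
  C$_\alpha$ atoms after optimal (Kabsch) superposition, in Angstrom. An
  optional per-residue clamp is available but off by default. Unclamped it
  equals `deviation_ca(mode = "mean")`.
* $L_{\mathrm{dist}}$ — cross entropy of the predicted distance distribution
  ("distogram") against the bin containing the true C$_\beta$–C$_\beta$
  distance (C$_\alpha$ for glycine), in nats. Binning follows the common
  64-bin convention: 63 edges uniform from 2.3125 to 21.6875 Å, open tails.
* $L_{\mathrm{pLDDT}} = 1 - \overline{\mathrm{pLDDT}}$ and
  $L_{\mathrm{pTM}} = 1 - \mathrm{pTM}$ — confidence penalties on the unit
  scale (0–100 inputs are rescaled at ingestion; only values above 2 are
  treated as percentage-scale, so malformed unit-scale values still error).

Default weights are $W_{\mathrm{FAPE}} = 1.0$, $W_{\mathrm{dist}} = 0.5$,
$W_{\mathrm{pLDDT}} = W_{\mathrm{pTM}} = 0.2$; reseeded ("soft start")
trajectories disable the distogram term (`loss_weights(soft_start = TRUE)`).

# The optimizer

Sequences are initialized from the target's secondary structure — alanine
for helix, valine for strand, glycine for loop — then 10% of positions are
randomly mutated (never to cysteine) to diversify trajectories. Each round:

1. the ensemble loss gradient with respect to the PSSM logits is computed
   and averaged over the five ensemble members;
2. the gradient is divided by its Frobenius norm and a bias-corrected ADAM
   step is applied (defaults `lr = 0.1`, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
   $\epsilon = 10^{-8}$);
3. the PSSM is decoded — row softmax with the cysteine column masked at
   $-10^9$, then argmax with ties to the lowest alphabet index — and the
   decoded sequence is what the predictor sees and what the per-iteration
   record stores. Recording the decode (rather than the soft PSSM) matters:
   it is the decoded sequence that is carried into redesign, so convergence
   must be a property of that sequence, not of the relaxed logits.

A trajectory converges when the decoded sequence's prediction reaches both
`tm_min` and `plddt_min` (defaults 0.8/0.8, mirroring the downstream filter
gates; convergence is not defined in terms of the loss because the gates are
what decide a design's fate). By default iteration stops at convergence;
`stop_at_convergence = FALSE` runs the full budget (500 rounds by default).

Two initialization details were genuinely open and were fixed as follows:

* **One-hot logit scale +2.** The starting PSSM puts +2 on each chosen
  letter. Saturating starts (+4 and above) freeze the initial random
  mutations in place before the gradient can correct them — on the bundle
  fixture the convergence rate drops visibly — while +2 keeps the softmax
  close to one-hot yet correctable. The scale is exposed as `init_scale`.
* **Frobenius normalization** of the whole gradient matrix (not
  per-position); a per-position variant would change only the relative step
  sizes between positions and was not needed.

# The toy folder

The toy predictor maps per-position amino-acid probabilities $q_i$ to
secondary-structure class propensities $s_i = q_i^\top P_m$ through a fixed
20 x 3 table $P$ (`toy_propensity_table()`): alanine is maximal for helix,
valine for strand, glycine for loop, and the other residues carry plausible
helix/strand/loop preferences. The five ensemble members use fixed ±2%
column perturbations of $P$ — constants, not random draws, so "mean of five"
behavior is exactly reproducible.

Coordinates are built by one shared ideal-geometry engine (`build_backbone`):
N, C$_\alpha$, C, O placed by NeRF chain extension with ideal bond lengths
and angles, helix torsions (−57°, −47°), strand torsions (−139°, 135°), and
a fixed position-indexed turn pattern for loops. Per position the toy blends
the three class torsions with weights $\mathrm{softmax}(\beta_b s_i)$,
$\beta_b = 16$; confidence is $\mathrm{pLDDT}_i = \max\,
\mathrm{softmax}(\beta s_i)$ with $\beta = 8$, and pTM is the mean pLDDT.
Two consequences are worth spelling out:

* a sequence whose letters all prefer the right class reproduces the
  target's ideal geometry essentially exactly (the blend saturates), so the
  design optimum coincides with the fixture geometry;
* coordinates are *continuous* in the logits. Building from hard argmax
  labels instead would make the structural loss terms piecewise constant and
  their finite-difference gradient zero almost everywhere, leaving only the
  confidence terms to drive design — which converges to confidently wrong
  folds. The sharpened blend keeps the landscape informative while staying
  within ~0.02 Å of the labeled geometry for pure sequences.

Gradients are numerical, not hand-derived: central finite differences with
step $10^{-4}$. The differences are taken on the per-position class
propensities — the only channel through which the loss depends on the
logits — and chained exactly through the fixed table $P_m$ and the softmax
Jacobian. This is the same derivative as naive per-logit differencing to
$O(h^2)$ at roughly a seventh of the cost; a naive per-logit reference
implementation is kept in the package and a test asserts agreement to
$10^{-6}$. The compute-heavy kernels (chain building, Kabsch superposition,
distogram terms, Shrake–Rupley surface) are in C++.

The toy distogram smooths a Gaussian of width 0.75 Å around each predicted
pairwise distance across the 64 bins; recycles (0 during design, 3 at
re-prediction, matching the usual predictor settings) sharpen the class
propensities ($s \mapsto s^{1.3}$, renormalized), raising confidence without
changing labels. An optional fixed context chain (e.g. a binder present
during conformation-specific design) is passed through unchanged as a
separate chain.

# Geometry and metrics

* **Superposition** is closed-form Kabsch (base `svd`), always proper
  (determinant +1). A property test checks the residual against a brute-force
  rotation-grid search.
* **Backbone deviation** is reported as the *mean* per-residue C$_\alpha$
  Euclidean distance after superposition (`mode = "mean"`), with classical
  root-mean-square as an option; mean ≤ rms always. The full-atom variant
  superposes and measures over the atom names shared by corresponded
  residues.
* **TM-score** implements
  $\mathrm{TM} = \frac{1}{L_{\mathrm{norm}}}\sum_i \frac{1}{1 + (d_i/d_0)^2}$,
  $d_0 = 1.24\,(L_{\mathrm{norm}} - 15)^{1/3} - 1.8$ floored at 0.5 Å,
  maximized by iterative distance-cutoff refinement from several seed
  fragments. The correspondence is an explicit input: the pipeline always
  compares equal-length design and target index-wise, so no
  sequence-independent alignment search is implemented (external structural
  aligner output can be parsed instead). Normalization defaults to the
  reference length; the score is capped at 1 so that degenerate
  normalization lengths below the number of corresponded pairs stay in
  (0, 1].
* **SASA** is Shrake–Rupley with a deterministic Fibonacci sphere (960
  points, <1% error on an isolated sphere), probe radius 1.4 Å, van der
  Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Å. Layers follow the usual
  convention: core < 20 Ų, surface > 40 Ų, boundary between. The surface
  hydrophobic fraction counts the apolar set exactly `GPAVILMFYW` among
  surface residues.
* **Secondary structure** is a self-contained Kabsch–Sander-style assigner:
  amide H inferred from the preceding carbonyl, H-bond energy
  $E = 0.084\,(1/d_{ON} + 1/d_{CH} - 1/d_{OH} - 1/d_{CN}) \cdot 332$
  kcal/mol, bond below −0.5; helices from consecutive n-turns (3, 4, 5
  collapsing to H), strands from parallel/antiparallel bridge patterns,
  everything else L.
* **Contact order** at the secondary-structure level: C$_\alpha$ pairs
  within 8 Å, at least 5 apart in sequence ("more than four residues"),
  spanning *distinct* secondary-structure segments; both the mean sequence
  separation and its length-normalized value are reported, and a flag marks
  structures with no qualifying contact (mean defined 0).

One wording in the source material defines both core and surface residues
as "less than 20 Ų"; this is internally inconsistent with the surface
hydrophobicity definition, and the package uses core < 20 / surface > 40
throughout.

# Inverse-folding stage

`sample_sequences()` implements the redesign contract: per-position
categorical sampling from sampler logits plus a bias vector
(`build_sampling_bias()`: +bonus on the polar set D,E,H,K,N,Q,R,S,T,Y,
−penalty on alanine — the polar set is a package choice, the sources do not
enumerate one), with fixed positions overwritten by their required letters,
cysteine masked, and optional Gaussian backbone noise (σ per axis) applied
first. Two sequences per backbone is the pipeline default.

Two mock samplers stand in for a neural inverse-folding model. The uniform
sampler is backbone-blind. The burial-aware sampler conditions on the
backbone in two coarse but honest ways: (i) letters whose preferred
secondary-structure class matches the *local backbone geometry* — classified
from measured φ/ψ torsions, not from hydrogen bonding, because torsions are
the local signal an inverse-folding model actually sees and they are exact
even at element boundaries where H-bond assignments fray — get a +8 logit
bonus; (ii) buried positions get a hydrophobic bonus and exposed positions a
polar bonus scaled by burial (SASA relative to an 80 Ų fully-exposed
reference). This is sufficient for the solubilization direction to be
testable end-to-end: redesigning the membrane-like bundle fixture lowers its
surface hydrophobic fraction from 1.0 to ≈0.1 in essentially every seeded
draw.

Functional (claudin-style) design is exposed as two presets over a
fixed-position file: redesign only the membrane-spanning surface (~40%
designable) or the whole membrane-spanning segment including its core
(~60% designable).

# Filters

Strict-inequality gates: TM > 0.80, mean pLDDT > 0.80, best e-value > 0.1;
the structurally harder rhomboid-class folds use 0.75/0.75. Queries absent
from the BLAST tabular output pass the novelty gate — no database hit is
maximal novelty. Values *at* a gate are rejected; the filter suite tests
this explicitly. Force-field relaxation of re-predicted models is out of
scope and recorded as skipped in each record's provenance field.

# Fixtures: what they emulate and what they do not

`generate_fixture()` provides deterministic, download-free stand-ins for
design targets with exact ground truth:

* `helix`, `strand`, `helix_bundle`, `membrane_like_bundle` are pure
  torsion-space constructions. Bundles are helix segments joined by a fixed
  turn-torsion pattern chosen once (from a clash-and-compactness search over
  candidate turn patterns) so that three- and four-helix chains fold back
  into packed bundles; because the fixture and the toy folder share one
  geometry engine, a converged design can reproduce its target exactly. The
  membrane-like bundle assigns hydrophobic letters to its exposed surface
  (surface fraction 1.0 by construction) over a hydrophobic core.
* `beta_hairpin`, `barrel_like`, `tim_like` are assembled from rigidly
  placed ideal strands with a partner transform calibrated once so that the
  backbone hydrogen-bond registry the assigner needs actually exists;
  connector residues are interpolated. `barrel_like` is an eight-strand
  up-down meander; `tim_like` alternates the eight strands with flanking
  helices on both faces — the strand–helix alternation that gives TIM-class
  folds their long-range contacts and their high contact order relative to
  an all-local helix bundle.

Ground-truth layer labels are derived from the constructed geometry via the
package's own SASA (deterministic, hence reproducible truth); ground-truth
secondary structure is the construction string. Two caveats define what
passing tests on fixtures do and do not show. First, ideal geometry has no
side-chain rotamers, no bond-length variance and no crystallographic noise,
so absolute SASA values and H-bond energies are cleaner than real data; the
package therefore tests *relationships* (thresholds, orderings, oracle
equivalence), not absolute biophysical accuracy. Second, at
secondary-structure element boundaries the hydrogen-bond-based assigner
frays by roughly one residue — as it does on real structures — so truth/assigner
agreement is asserted at ≥90% over element-interior residues; a lone
extended strand is the limiting case, which the assigner must read as all-loop
(no partners) even though its construction truth is strand.

# Pipeline determinism

One global seed drives everything: per-stage seeds are derived by a stable
32-bit FNV-1a hash of (seed, stage name, index), all below $2^{31}$. Every
user-facing random operation takes an explicit seed, saves and restores the
global RNG state, and is bitwise reproducible; reports contain no
timestamps, so identical configurations yield byte-identical artifacts. The
report carries a config hash (output directory excluded) for provenance.

# Problem sizes and runtime

The default test and acceptance workloads use a 40-residue three-helix
bundle for design (10 seeded trajectories, 500-round budget, early stop at
convergence) and a 60-residue four-helix membrane-like bundle for
solubilization; these sizes exercise every code path while a full 10-seed
design study completes in a few minutes on one CPU. Convergence on this
landscape is high but deliberately not perfect — roughly 9 of 10 seeds; the
stuck seeds sit in genuinely coupled local minima (every single-position
correction raises the loss), which is exactly the failure mode that
motivates soft starts: reseeding from mutated converged sequences with the
distogram term disabled.

# Known limitations

* The toy folder is a three-class torsion model: it cannot represent
  register shifts, domain motions, or side-chain packing, and its pTM
  degenerates to mean pLDDT. It validates pipeline mechanics and metric
  implementations, not designability of real folds.
* TM-score requires a supplied correspondence; it is not a structural
  aligner.
* The secondary-structure assigner covers the 3-state collapse of the
  standard 8 classes; π-helix and bend subtleties are absorbed into H/L.
* mmCIF support covers the `atom_site` loop (coordinates, occupancies,
  alternate locations, first model), not the full dictionary.
* Inverse folding is a mock contract. Plugging in a real network requires
  only the `(backbone) -> N x 20 logits` sampler interface, but no such
  adapter ships here.
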