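---
title: "Methods: enrichment metrics and structural accuracy for receptor-model benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment metrics and structural accuracy for receptor-model benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockbench)
```

## Scope

dockbench implements the retrospective evaluation machinery used to judge
receptor structure models (typically GPCR homology models) for
structure-based virtual screening:

* semi-log ROC ligand-enrichment scoring (logAUC and the adjusted aLogAUC),
* ensemble enrichment by best-score merging over sets of binding-site models,
* chemotype-subset enrichment,
* region-wise structural accuracy (TM backbone, binding-site backbone,
  symmetry-corrected binding-site side chains),
* region-restricted sequence identity from pairwise target-template
  alignments,
* geometric Good/Bad classification of docked binding modes, and
* the summary statistics used to compare templates (quantiles, Pearson
  correlation, improvement fractions).

It deliberately does **not** dock, build homology models, generate decoys,
or run molecular dynamics. Docking score tables, receptor coordinates,
alignments and poses enter as plain text; a synthetic-data module generates
statistically controlled stand-ins for all of them so the whole stack runs
and is testable without any external data.

## The enrichment metric

A retrospective screen docks known ligands and property-matched decoys
against one binding-site model and ranks all successfully docked compounds
by predicted binding energy (lower = better). Walking down that ranking
traces a ROC curve: the fraction of ligands retrieved (TPR) against the
fraction of decoys retrieved (FPR, the x axis).

Virtual screening only ever tests the top of a ranked library, so the area
under the plain ROC curve is a poor figure of merit. The semi-log AUC
instead integrates the curve against $\log_{10} x$:

$$
\mathrm{logAUC}_\lambda
  = \frac{100}{\log_{10}(1/\lambda)}
    \int_{\lambda}^{1} \mathrm{TPR}(x)\, d(\log_{10} x),
$$

which up-weights early retrieval. Random selection ($\mathrm{TPR}(x) = x$)
has the closed form $100\,(1-\lambda)/\ln(1/\lambda)$; the **adjusted**
logAUC (aLogAUC) subtracts it, so random screens score 0, a perfect screen
scores $100 - \mathrm{random}$, and negative values indicate
anti-enrichment. A useful calibration: the curve that retrieves exactly
twice the random ligand fraction at every decoy fraction,
$\mathrm{TPR}(x) = \min(2x, 1)$, scores almost exactly 10 aLogAUC
percentage points at $\lambda = 0.001$:

```{r doubling}
adjusted_log_auc(data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 1, 1)))
```

Results are banded qualitatively: below 10 poor, 10-15 fair, above 15 to
20 good, above 20 to 25 very good, above 25 excellent. Upper band edges
are inclusive and 10 itself is "fair", following the band notation
literally where it is unambiguous.

### Numerical conventions

Three conventions are genuinely open in this metric family; dockbench
fixes them as follows and exposes each as an argument:

* **$\lambda$, the lower bound of the log axis.** Default 0.001, the
  established convention for this metric. With fewer than
  $1/\lambda$ decoys the left edge of the integral is carried by the first
  curve segment, which is why large decoy sets are preferred.
* **Interpolation and integration.** The TPR is linearly interpolated
  between ROC points on the linear FPR axis and each linear piece is
  integrated against $d(\log_{10}x)$ *in closed form*
  ($\int (a + bx)\,d\ln x = a \ln x + b x$), so the reported value is exact
  for the interpolated curve; there is no quadrature grid to tune. The
  test suite checks this against an independent fine-grid Simpson
  quadrature on 1,000 random tables at $10^{-6}$ tolerance.
* **Ties and docking failures.** Compounds sharing a score advance FPR and
  TPR as one simultaneous block, which makes the curve independent of
  record order. Compounds that failed to dock stay in the denominators and
  are appended as one final tied block: a screen that cannot dock its
  ligands is thereby penalized rather than flattered. Whether the original
  studies excluded undocked compounds from denominators is generally not
  reported; keeping them is the conservative choice.

## Ensemble and chemotype-subset enrichment

Ensemble docking evaluation assigns each compound its most favorable
(lowest) energy across the member models and scores the merged table as a
single screen (`merge_best_score()`, `ensemble_enrichment()`). The merge
requires a shared compound universe, is invariant to member order and
duplication, and reduces to the member itself for $k = 1$; a member that
supplies every best score determines the ensemble exactly.

Chemotype subsets (e.g. ligands similar to a template's co-crystallized
ligand) enter as explicit id lists. `subset_enrichment()` rescores the
screen counting only subset members as actives: all decoys are retained,
and non-subset ligands are removed from both numerator and denominator
rather than recast as decoys — they are known actives and would
contaminate the negative set. The similarity clustering that defines such
sets is outside the package's scope.

## Structural accuracy metrics

`rmsd_report()` computes the standard accuracy triple of a model against a
reference structure: RMSD over the TM backbone (N, CA, C, O), the
binding-site backbone, and the binding-site heavy side-chain atoms (CB
included, OXT and hydrogens never used). The protocol behind published
RMSD values of this kind is rarely stated in full; dockbench uses one
deterministic, documentable convention:

* a single least-squares (Kabsch/SVD, reflection-guarded) fit on the TM
  backbone, with atoms paired strictly by (chain, residue number, atom
  name) and atoms missing from either structure skipped symmetrically;
* both binding-site metrics evaluated in that frame with no refit and no
  outlier-rejection cycles.

Side-chain RMSDs are symmetry-corrected: for residues whose terminal
groups are chemically indistinguishable under a 180° flip — Asp (OD1/OD2),
Glu (OE1/OE2), Phe/Tyr (CD1/CD2 with CE1/CE2), Arg (NH1/NH2), Leu
(CD1/CD2), Val (CG1/CG2) — the labeling with the smaller squared deviation
is chosen per residue, independently (the flip couples the two ring pairs
of Phe/Tyr, so they swap together). This is exact and linear-time, and
guarantees the corrected RMSD never exceeds the naive one. Because the
choice is per residue, published values computed with other tools are
reproduced in convention, not bit-for-bit.

`pairwise_diversity()` applies the same machinery to every pair of a model
set (each pair superposed on the TM backbone first) and reports the
off-diagonal mean — the usual summary of how much models built from one
template differ. `improvement_fraction()` reports the fraction of
candidate structures (e.g. MD snapshots) strictly closer to the reference
than a baseline model, the statistic used to judge refinement protocols.

## Region-restricted sequence identity

`region_identity()` computes percent identity between target and template
over a named set of target residue numbers (TM bundle, binding site). The
denominator is the *target region size*, not the aligned-column count: a
region residue aligned to a template gap counts as a mismatch, so gaps in
structurally critical regions penalize the template. Comparison is
case-insensitive and `X` never matches. Binding-site definitions and
Ballesteros-Weinstein position lists enter as configuration (a named map
from BW labels such as `"3.32"` to author residue numbers), never
hard-coded.

## Binding-mode classification

The conserved aminergic binding mode has two geometric signatures: a salt
bridge from a protonated amine to the anchor aspartate (BW 3.32) and an
aromatic moiety extending toward the TM5/TM6 face. `classify_pose()`
declares a pose **Good** iff both are present, **Bad** otherwise, which is
how top-ranked poses are tallied when judging whether a model binds
ligands in the right place at all.

The published criteria are qualitative (they were applied by visual
inspection), so the thresholds here are conventional interaction-geometry
defaults, exposed as arguments: 4.0 Å for the minimum cation to
carboxylate-oxygen distance and 6.0 Å for the minimum ring-centroid to
anchor-atom distance. The TM5/6 anchor residues are user configuration
(helices, not residues, are named in the criterion). Cation and ring
perception is input metadata (a YAML side-car next to the pose file); no
chemical perception engine is involved. A pose with no declared cation or
ring raises a criterion-inapplicable error instead of silently scoring
Bad. Any reproduction of published Good/Bad counts is threshold-sensitive
by nature.

## The synthetic-data module

The generators produce inputs with the statistical structure the analysis
assumes, so every stage runs with no downloads:

* `gen_screen()` draws ligand and decoy scores from
  $N(\mu_L, \sigma)$ / $N(\mu_D, \sigma)$ — the minimal (binormal) family
  with a closed-form ROC, $\mathrm{TPR}(x) = \Phi(\Phi^{-1}(x) + d)$ with
  $d = (\mu_D - \mu_L)/\sigma$. `binormal_logauc_oracle()` integrates that
  analytic curve numerically and shares no code with the empirical path,
  giving an independent expectation for simulated screens. Defaults mirror
  a large aminergic benchmark: 822 ligands versus ~55k property-matched
  decoys, docking energies near -35 kcal/mol with spread 5, one-sigma
  class separation. Docking failure is assigned independently of score —
  the simplest null for the undocked-handling policy.
* `gen_ensemble()` adds a latent per-compound score, a per-model bias and
  per-compound-model noise (default 50 models per template, the usual
  evaluation depth; implied inter-model correlation
  $\sigma^2/(\sigma^2 + \tau^2)$, 0.5 at the defaults). Minimizing over
  correlated members shrinks the noise contribution, which is why ensemble
  enrichment tends to beat the member median — the suite verifies this in
  at least 95 of 100 replicates.
* `gen_toy_structure()` / `gen_perturbed_structure()` build a
  deterministic helical peptide (all symmetric-side-chain types included)
  and displace each heavy atom by iid $N(0, \sigma)$ per coordinate, so
  the RMSD concentrates on $\sqrt{3}\sigma$; symmetric relabeling without
  movement probes the symmetry correction.
* `gen_toy_complex()` places anchors, cation and ring at exactly requested
  distances; `gen_toy_alignment()` builds alignments whose region identity
  is exactly $100\,n_\mathrm{match}/n_\mathrm{region}$ by construction.

What the generators do **not** emulate: docking energy landscapes and
their heavy tails, property matching between ligands and decoys,
correlations between score and docking failure, real side-chain rotamer
statistics, or loop conformational variability. Passing tests therefore
demonstrate the correctness of the metrics and their algebra under a
controlled statistical model, not the screening performance of any real
receptor.

## Problem sizes and reproducibility

All generators take explicit integer seeds, restore the caller's RNG
stream, and write the same dialects the readers consume, so
simulate-to-report pipelines are byte-reproducible (`run_pipeline()`
writes a manifest with the config hash and seed). The test suite exercises
the statistical properties at sizes chosen to keep Monte-Carlo error well
below the tested effects while remaining quick on one CPU: null and
separation calibrations use 200 ligands against 10,000 decoys over
30-100 replicates; the ensemble-versus-median property uses 8 models of
150 ligands against 3,000 decoys over 100 replicates; structural
calibrations use ~560-atom toy structures where the relative sampling
error of the RMSD is about 1-2%.

## Known limitations

* aLogAUC values depend on decoy-set size near the $\lambda$ edge; values
  computed with very small decoy sets are not comparable to benchmark-scale
  values.
* Atom pairing requires shared residue numbering; sequence-based
  structural alignment of differently numbered structures is out of scope.
* The symmetry correction covers the standard two-fold side-chain
  ambiguities only; His ring flips (which exchange C/N) and full
  combinatorial relabeling are not considered.
* Pose classification is purely geometric; it does not score pose quality
  continuously and cannot exceed the information in the declared cation
  and ring annotations.
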