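---
title: "Phenotypic trajectory analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic trajectory analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotrack)
```

# The problem

High-content screens measure a few dozen morphological and intensity
features on every segmented cell in every well of a compound-treated plate.
Two observations complicate turning such tables into mechanism-of-action
(MoA) calls. First, the informative phenotypic variation is often small
relative to dominant but uninformative cell-to-cell variability (cell-cycle
stage, spreading, staining efficiency), so variance-ranked decompositions
like PCA bury it. Second, a compound's phenotype changes with dose: two
compounds with the same mechanism but different potency trace the same
*phenotypic trajectory* through feature space, entered at different points
of their serial-dilution series. A useful similarity measure must therefore
be insensitive to potency (shifts along the dose axis) and must not reward
two compounds for both looking like untreated cells.

`phenotrack` implements an analysis pipeline built around these two ideas:
discriminative ("over-classed" LDA) dimensionality reduction, and a
dose-order-preserving trajectory similarity (MSWO) that attenuates
near-control phenotypes; plus the downstream clustering and exemplar
classification, and a synthetic-screen generator so that the whole chain is
testable against known ground truth.

# Preprocessing

**Transforms.** Sizes, areas and intensities are right-skewed and are log
transformed (`x -> log(x + eps)`); shape factors confined to `[0, 1]` go
through a logit after clamping to `[eps, 1 - eps]`. `eps = 1e-6` on the
native scale: small enough to leave typical values untouched, large enough
to keep every output finite. The transform map is data (`apply_transforms()`
takes a named spec); `infer_transform_spec()` guesses it from ranges and
`screen_transform_spec()` states it for the generator's panel.

**Stain background.** One intensity feature (in the motivating assay, the
DNA-damage marker read in the 488 nm channel) can vary multiplicatively
from well to well for purely technical reasons. From a feature table alone
the background image intensity is not recoverable, so
`normalize_stain_background()` divides by a per-well robust proxy: the 10th
percentile of the feature across the well's cells. Whether the original
correction divided, subtracted, or subtracted in log space is not
determinable from the source material; division by a supplied or estimated
per-well background is the default and both the background vector and the
percentile are arguments. On the synthetic screens (where the artifact is
injected multiplicatively) the proxy removes nearly all between-well
variance of the feature; the estimation noise of a within-well percentile
(~`0.2` log-units at 80 cells/well) is the floor on what it can achieve.

**QC.** The highest tested concentration of each compound can be dropped
(`drop_top_level`), reflecting the noisiness of top doses (precipitation,
edge effects); the generator's default 9 levels represent a 10-point series
with the top dose already excluded, so the end-to-end defaults leave this
off. Contaminated wells are flagged by a robust z-score on the per-well
mean nuclear stain: `median + z * MAD` over all wells, default `z = 5`. The
source material gives no numeric cut ("well above the observed
distribution"); `z = 5` is conservative and exposed as a parameter. Note
that strongly cytotoxic doses legitimately shift nuclear stain, so on
screens with large effects an occasional active well trips the filter; this
is the intended robust behavior, not an error.

**Plate normalization.** Per plate and feature, the mean over control cells
is subtracted from every cell. This makes every plate's control mean
exactly 0, which the control-weighted overlap below takes as a premise, and
removes additive plate-to-plate offsets.

# Over-classed LDA

Multi-class LDA ranks directions `v` by the generalized Rayleigh quotient
of between-class to within-class scatter, i.e. solves `Sigma_b v = lambda
(Sigma_w + ridge I) v`. Instead of grouping cells by annotated mechanism
(subjective, and circular for classification), every (compound,
concentration) pair is its own class and all controls form one more class.
With hundreds of classes and ~23 features the problem is "over-classed":
the point is not a (k-1)-dimensional discriminant but a *ranking* of
feature-space directions by how well they separate treatments. Dose-to-dose
variation of one compound is deliberately between-class variation, so
directions along which trajectories move score highly.

Choices a reader may want to audit:

* **Weighting.** The scatter matrices are cell-count weighted ("pooled"):
  `Sigma_w` is the pooled covariance of cells about their class means and
  `Sigma_b` the count-weighted covariance of class means about the grand
  mean, both with denominator N, so `Sigma_w + Sigma_b` equals the total
  covariance exactly (a tested identity). The source material says only
  "average"; an unweighted variant (plain average of per-class covariances
  and of class means) is provided via `weighting = "unweighted"`.
* **Ridge.** Over-classed designs can make `Sigma_w` ill-conditioned;
  `ridge = 1e-6 * trace(Sigma_w)/d` by default, exposed.
* **Orientation and scale.** Eigenvectors are returned with Euclidean unit
  norm (the `Sigma_w`-metric normalization would be equally defensible;
  eigenvalues and subspaces are identical) and signed so the
  largest-magnitude loading is positive, for reproducible plots and tests.
* **Controls** form one class for the whole screen, not one per plate:
  plate normalization has already removed plate effects.
* **Default dimensionality** is `m = 16`, the bias-variance sweet spot
  for mechanism classification in the motivating assay; `m` is a parameter
  everywhere and the comparison utilities sweep it.

For comparison the package also fits mechanism-class LDA (all doses of all
compounds of a class pooled into one class, controls and unmapped compounds
in a null class; at most k-1 informative dimensions) and PCA. PCA scales
every feature to unit variance first; the returned loadings fold that
scaling in so that projection stays purely linear and mean-zero control
populations stay mean-zero in projected space (no per-projection centering).

# Trajectories and similarity

**Gaussian summaries.** Cells are pooled across replicate plates per
(compound, level) — per-plate weighting is not described in the source
material, and pooling maximizes the cells behind each covariance — and
summarized as `(mean, covariance, n)`. Covariances are shrunk toward their
diagonal (`s = 0.1`), blended halfway to a scaled identity when `n < m + 2`,
and floored by `1e-8 * mean(diag)` on the diagonal: the overlap below needs
nonsingular covariances, and regularization of the original covariances is
an artifact decision (nothing in the source constrains it). Levels with
fewer than `min_cells = m + 2` cells are flagged *degenerate*: they keep
their cell count in all denominators but contribute zero overlap, so
wiping out cells depresses similarity to compounds that retain them.
Zero-cell levels (complete kill) are recorded with `n = 0` and never match.

**Overlap.** For two Gaussians,
$$O(D_1, D_2) = \frac{|4\Sigma_1\Sigma_2|^{1/2}}{|\Sigma_1+\Sigma_2|}
\exp\!\left(-\tfrac12(\mu_1-\mu_2)^T(\Sigma_1+\Sigma_2)^{-1}
(\mu_1-\mu_2)\right),$$
computed with Cholesky log-determinants and clamped to `[0, 1]`. The
radical's placement is the only reading under which identical distributions
give exactly 1 (it is the squared Bhattacharyya coefficient, a tested
equivalence in 1-D). The *weighted* overlap multiplies by
`(1 - O(D_1, D_0))(1 - O(D_2, D_0))` with `D_0` the pooled control
distribution, so similarity between near-control populations is suppressed.

**MSWO.** The similarity of two dose-ordered trajectories is the maximum,
over equal-length order-preserving (not necessarily consecutive) index
subsequences, of the summed cell-count-weighted weighted overlaps, divided
by the total cell count of both trajectories. The recursion
`SO(k, l) = (N_{i,k} + N_{j,l}) O_W(D_{i,k}, D_{j,l}) + max_{k'<k, l'<l}
SO(k', l')` is evaluated in `O(L^2)` with prefix maxima (`mswo_dp()`); an
exhaustive enumerator (`mswo_bruteforce()`, trajectories up to 8 levels)
exists purely as an independent oracle and the two are held equal to
`1e-12` in the tests. Skipping levels is what buys potency invariance: a
compound entering the same track two dilutions later matches through a
non-consecutive subsequence of the more potent compound's doses. Ablation
switches reproduce the degraded variants: `weighted = FALSE` (simple
overlap inside MSWO) and `single_point = TRUE` (highest usable level only).

**Phenotypic activity** is the count-weighted mean of `1 - O(D_k, D_0)`
across the trajectory: how unlike untreated cells the compound's phenotype
is, on `[0, 1]`. Degenerate levels count as maximally unlike (overlap 0) —
a fully cytotoxic series is maximally active, which matches how such
compounds behave in the assay.

# Clustering and classification

**UPGMA** runs on `d = 1 - s` (the natural bounded conversion; the source
states UPGMA on similarities without fixing one). The implementation is
in-package rather than `stats::hclust(method = "average")` in order to pin
tie-breaking: clusters are represented by their lexicographically smallest
member and the smallest representative pair merges first, making the tree
invariant to input order. The result is `hclust`-compatible (plot,
`cutree`), heights agree with `hclust` to `1e-12` in tests, and
`to_newick()` exports an ultrametric tree with node elevations at half the
merge distance.

**Exemplars.** A mechanism class is usable only with at least 4 members of
phenotypic activity above 0.4; those members are its exemplars. A
compound's similarity to a class is the mean MSWO to its exemplars; the
best class is the arg-max.

**The Unspecified threshold.** Best scores are normalized by phenotypic
activity — implemented as division, the simplest reading of "normalized to
each compound's phenotypic activity" (regression or standardization are
defensible alternatives; division is the default and the normalization is
confined to one place in the code) — floored at `1e-6`, and logged. Gaussians
are fitted to the classified and unclassified groups and the decision
boundary given prior `p_c` becomes the threshold `m_t`. Two forms are
implemented:

* `method = "printed"` (default): the elegant closed form
  `log m_t = (sigma_c mu_u + sigma_u mu_c)/(sigma_c + sigma_u)` at
  `p_c = 0.5`, and for general priors a quadratic-root form whose radical
  carries `log(s2_c/s2_u * p_c/(1-p_c))`.
* `method = "exact"`: the exact two-Gaussian MAP boundary, i.e. the root of
  `p_c N(x; mu_c, s2_c) = (1-p_c) N(x; mu_u, s2_u)` between the group
  means, whose radical carries `log(s2_c/s2_u * ((1-p_c)/p_c)^2)`.

The printed simple form is the exact boundary with the log-variance term
dropped, and the printed general form substitutes the prior/variance term
under the radical; the tests verify the exact form against a bisection
oracle to `1e-9` and bound the printed form's displacement by the radical
substitution. When the two variances coincide both methods use the analytic
limit `log m_t = (mu_c + mu_u)/2 + s2 log(p_c/(1-p_c))/(mu_c - mu_u)`,
since the quadratic degenerates. `p_c = "auto"` uses the observed fraction
of compounds annotated with an exemplar class.

**Leave-one-out contract.** When compound X is scored, X is removed from
every exemplar list and from the threshold fit (and from the `p_c = "auto"`
proportion). The prediction rule is exactly: best class if the normalized
score reaches `m_t`, else `"Unspecified"`.

# The synthetic world

`generate_screen()` emits the post-image-analysis artifact of a screen —
a per-cell feature table — with known ground truth. What it emulates, with
defaults and why:

* **Design**: 5 mechanism classes x 8 compounds + 6 idiosyncratic
  compounds, 9 retained concentration levels (a 10-point, 3-fold dilution
  series with the noisy top dose pre-excluded), triplicate plates, 300
  cells per control well — the scale of the motivating assay.
* **Tracks**: each class follows a smooth 2-component curve in a latent
  space (`latent_dim = 10`) mixed into the 23 features by a random
  orthonormal map drawn once per screen (identifiability and exact
  reproducibility). Track shapes alternate `monotone` (norm nondecreasing
  with dose) and `rise-and-return` (interior peak, as DNA-damage responses
  that fade at cytotoxic doses). `effect_amplitude = 4` population-SDs at
  top dose: strongly active compounds in real screens reach activities near
  1, which requires mean shifts of several within-population SDs.
* **Potency**: each compound shifts its class track along the dose axis by
  `N(0, 0.75)` levels (linear interpolation between template points),
  mimicking left/right shifts of a serial dilution.
* **Cytotoxicity**: cell counts decay with a Hill curve (half-kill at level
  7, slope 3) for active compounds; wells can round to zero cells and are
  then emitted as empty.
* **Nuisance structure**: additive per-plate offsets (`sd 0.3`), a
  multiplicative per-well background on one stain feature (`sd 0.3` in
  log), isotropic per-cell noise (`sd 1`), and — crucially for the LDA/PCA
  comparison — 3 *structured* cell-to-cell variation directions
  (`sd 3`) orthogonal to every track: large, correlated,
  mechanism-uninformative variability (cell cycle, spreading) that
  dominates the leading principal components while the class signal lives
  partly in low-variance directions.
* **Negative controls of the design**: the last class is generated
  near-control (15% amplitude) to emulate phenotypically inactive classes,
  and idiosyncratic compounds alternate between active (own private track)
  and inactive.

What it does **not** emulate: images or segmentation error, edge effects
and within-plate spatial structure, non-Gaussian subpopulations (e.g.
mitotic arrest as a mixture), compound-specific covariance changes beyond
the track geometry, or the real screen's class list. A green end-to-end
test therefore establishes that the pipeline recovers the structure this
world contains — potency-shifted shared tracks under realistic nuisance
variation — not that it reproduces any particular real screen's accuracy.

# Numerical and serialization choices

Log-determinants and quadratic forms via Cholesky; overlaps clamped to
`[0, 1]`; eigen-solvers symmetric with deterministic sign fixes; all
generator randomness derived from one integer seed through an RNG whose
state is saved and restored, so identical configurations are byte-identical
and library calls never perturb the caller's stream. Sidecar files (bases,
trajectories, QC reports, configs) are JSON via `jsonlite`; JSON was chosen
over YAML to keep the dependency footprint to packages guaranteed in the
analysis environment. The command-line interface
(`inst/cli/phenotrack.R`) is a thin `optparse` wrapper over the exported
functions.

# Known limitations

* The Gaussian summary discards subpopulation structure; strongly bimodal
  wells are represented by an inflated covariance.
* The percentile background proxy needs reasonably populated wells
  (its estimation noise scales as `1/sqrt(n)`); with very few cells per
  well, supply measured backgrounds instead.
* The contamination filter assumes most wells are clean; screens where a
  majority of wells shift the nuclear stain need a higher `z` or manual
  well lists.
* `p_c = "auto"` inherits whatever bias the annotation has; with tiny
  unclassified groups the threshold fit is unstable (at least 2 compounds
  per group are required, more are advisable).
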