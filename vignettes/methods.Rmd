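---
title: "Codon-model selection analysis over pathway networks: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-model selection analysis over pathway networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`phylosel` implements a system-level molecular-evolution analysis for a set
of protein-coding genes that together form a signaling pathway.  For each
gene it estimates the strength of selective pressure as
$\omega = d_N/d_S$, the ratio of the nonsynonymous to the synonymous
substitution rate, under Goldman–Yang-style codon substitution models fitted
by maximum likelihood on a fixed species phylogeny.  It then tests for
positive selection with nested likelihood ratio tests (site models and the
branch-site model), locates candidate sites with Bayes Empirical Bayes
posteriors, and finally asks how the per-gene selective pressures are
distributed over the system: do they correlate with a protein's position in
the pathway's interaction network, and do they differ between functional
classes of proteins?

## The codon substitution model

The state space is the 61 sense codons of the universal genetic code (stops
TAA, TAG, TGA are excluded; the code table is injectable for other codes).
The instantaneous rate from codon $i$ to $j$ is

$$
q_{ij} = \begin{cases}
0 & \text{more than one nucleotide change} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\omega \kappa \pi_j & \text{nonsynonymous transition}
\end{cases}
$$

with $\kappa$ the transition/transversion rate ratio and $\pi$ the
equilibrium codon frequencies.  $Q$ is rescaled so the expected
substitution rate at equilibrium is one; branch lengths are therefore in
expected substitutions per codon.  The model is time-reversible, which the
implementation exploits twice: transition probabilities
$P(t) = e^{Qt}$ come from the symmetric eigendecomposition
$\mathrm{diag}(\sqrt{\pi})\,Q\,\mathrm{diag}(1/\sqrt{\pi})$, and the
likelihood is invariant to root placement (asserted in the tests as the
pulley principle).

**Codon frequencies.** The default is F3x4: position-specific nucleotide
frequencies estimated from the alignment, multiplied and renormalized over
sense codons.  A pseudocount of 0.5 per nucleotide keeps all frequencies
strictly positive, which the eigendecomposition requires.  F61 (empirical
codon frequencies) and uniform frequencies are selectable.  F3x4 is the
convention of the standard tool chain for this analysis and was chosen for
that reason; nothing in the pipeline depends on the choice beyond the usual
sensitivity of $\hat\omega$ to frequency misspecification.

## Site-class models

All models are finite mixtures over site classes; a site's likelihood is the
class-weight-weighted sum of pruning likelihoods under the class's
$\omega$:

* **M0** — one ratio: a single $\omega$ for all sites and branches.
* **M1a** — nearly neutral: $\omega_0 \in (0,1)$ with weight $p_0$, and
  $\omega_1 = 1$.
* **M2a** — positive selection: M1a plus a class at $\omega_2 \ge 1$.
* **M7** — $\omega \sim \mathrm{Beta}(p, q)$, discretized into $K = 10$
  equal-weight categories, each represented by its bin median
  ($q_{(k-1/2)/K}$ quantiles).  $K$ and the bin representative are
  configurable; the median is less extreme than the bin mean in the tails
  and is the convention of the reference implementation.
* **M8** — M7 plus a class at $\omega_s \ge 1$ with weight $1 - p_0$.
* **Branch-site model A** — one *foreground* branch (marked with a
  codeml-style `#1` label suffix in Newick, or [tag_foreground()])
  against the background rest of the tree.  Four site classes:
  class 0 ($\omega_0$ everywhere), class 1 (neutral everywhere), class 2a
  (background $\omega_0$, foreground $\omega_2 \ge 1$) and class 2b
  (background 1, foreground $\omega_2$).  The proportions of 2a and 2b are
  tied to $p_0 : p_1$.  The null model fixes $\omega_2 = 1$.

For mixtures the per-class rate matrices share $\kappa$ and $\pi$ and one
common scale, computed from the background mixture, so that branch lengths
keep a single interpretation across classes.  Note that with $\omega_2 = 1$
the branch-site null does *not* reduce to M1a: class 2a still distinguishes
foreground (neutral) from background ($\omega_0$).  The exact reductions
that do hold — class 2b coincides with class 1, and the full collapse when
the foreground branch length is zero — are asserted in the test suite.

## Likelihood, optimization, derived rates

The likelihood is computed by Felsenstein pruning over unique site patterns
(compressed with multiplicities), in C++ (RcppArmadillo), with per-pattern
column rescaling against underflow.  Gap or ambiguous codons are missing
data: their tip partial vectors are all-ones, i.e. the likelihood
marginalizes over that tip's state.  Inputs are treated as pre-cleaned
alignments, so residual gaps are missing data rather than triggers for
column filtering.

Optimization is L-BFGS-B over log-transformed positive parameters
(branch lengths, $\kappa$, $\omega$, beta shapes) and logit/stick-breaking
transformed proportions, with box constraints implementing each model's
parameter ranges ($\omega$ capped at 50 to prevent divergence on saturated
data).  Branch-length gradients are analytic — a second, pre-order pruning
pass yields $\partial \ln L / \partial t_e$ for every branch at roughly the
cost of three likelihood evaluations — while the few remaining parameters
use forward differences.  Convergence is declared at a relative
log-likelihood change of about $10^{-8}$ (`factr = 1e8`).  Each fit is
repeated from starting $\omega \in \{0.1, 1.0, 2.0\}$ (configurable,
including replicate fits with jittered starting branch lengths) and the best
replicate kept, with every start's log-likelihood recorded in the fit object
for auditing.  Alternative models in a nested test are warm-started from the
null's optimum (branch lengths and embedded parameters); if optimizer noise
still leaves the alternative below the null, the fit is retried from the
null's parameter vector and the test statistic is clamped at zero.

When both a species tree and a gene tree are plausible, `choose_tree()`
fits M0 on every candidate and keeps the tree with the higher maximized
likelihood, breaking ties by input order.

From an M0 fit, `estimate_rates()` derives tree totals: with tree length
$T$ (substitutions per codon), the fitted $Q$ splits the substitution flux
into synonymous and nonsynonymous fractions, while the proportions of
synonymous and nonsynonymous *sites* are evaluated at $\omega = 1$
(mutational opportunity), so that $d_N/d_S$ reproduces the fitted $\omega$
exactly.  Identical sequences collapse the tree to length
zero; this is reported as a degenerate fit with a warning and
$\hat\omega$ marked non-identifiable, not as an error.  $d_N$ and $d_S$ are
reported as totals over the whole tree (not per-branch averages).

## Tests of positive selection and multiple testing

Site tests compare M1a vs M2a and M7 vs M8, each by a likelihood ratio test
with 2 degrees of freedom; the branch-site test compares model A against its
$\omega_2 = 1$ null with 1 degree of freedom.  The branch-site p-value uses
the plain $\chi^2_1$ tail per that convention; because the null puts
$\omega_2$ on the boundary, both tests are conservative, which the
calibration tests verify empirically.  Correction for multiple testing is
Benjamini–Hochberg by default (Holm and Bonferroni selectable), applied in
two families mirroring the study design: across genes for each site-model
comparison, and across all gene-by-branch combinations for the branch-site
tests.  The branch-site family defaults to the labelled internal branches of
the tree, configurable to any branch set.

## Bayes Empirical Bayes site posteriors

For a significant alternative fit, the per-site posterior that the site
evolves with $\omega > 1$ is averaged over a uniform prior grid on the
mixture parameters, with 10 points per free dimension: for M2a the
$(p_0, p_1)$ simplex (cell centers with $p_0 + p_1 \le 1$), $\omega_0$ on
$(0,1)$ and $\omega_2$ on $(1, 11)$; for M8 $p_0$ and $\omega_s$ (beta
shapes at their MLEs); for branch-site A the simplex and $\omega_2$
($\omega_0$ at its MLE).  Branch lengths and $\kappa$ stay at their MLEs
throughout, so the grid reuses one set of per-$\omega$ site likelihoods.
The plug-in NEB posterior is always computed alongside for comparison; on
informative data the two agree closely (asserted in the tests), while BEB is
the defensible choice when parameter uncertainty matters.

## Network topology and the association battery

The pathway is an undirected simple graph of experimentally supported
protein-protein interactions (stable complexes and transient interactions
alike; edges are unweighted presence indicators).  Reported measures:
degree; closeness centrality in the within-component convention
$(n_c - 1) / \sum_u d(v, u)$ — the curated network is connected, and on
disconnected synthetic graphs the function warns and computes per
component; betweenness centrality over unordered pairs with endpoints
excluded, equal-length shortest paths sharing weight (Brandes algorithm via
igraph, verified against exhaustive path enumeration); and a normalized
betweenness variant.

The association battery computes Spearman rank correlations of
$\{\omega, d_N, d_S\}$ against closeness, betweenness, degree and protein
length; Kruskal–Wallis rank-sum tests across the three gene
classifications (photoreceptor cell type: rod/cone/shared; process:
development/phototransduction/retinoid cycle; function: nine classes); and
the correlation of each network gene's rate with the mean rate of its
immediate neighbors.  Missing values are deleted listwise per statistic —
genes absent from the network (the retinoid-cycle and developmental
periphery) simply drop out of the topology correlations, so each analysis
reports its own $n$.  P-values here are reported uncorrected, as is
conventional for this descriptive layer; the report metadata says so
explicitly.  Spearman p-values use the t approximation for $n \ge 10$ and
exact permutation enumeration below (sampled permutations for $n = 9$); the
Kruskal–Wallis statistic is tie-corrected with $\chi^2_{k-1}$ tails.

## The synthetic study generator

Because the analysis is exercised end-to-end on synthetic data, the
generator is first-class, tested code.  Its defaults describe the study
conditions: nine mammals (human, chimpanzee, gorilla, orangutan, macaque,
marmoset, mouse, rat, dog) on a fixed unrooted topology with branch lengths
totalling about 1.85 substitutions per codon — plausible for mammalian
coding sequence — with the great-ape and rodent ancestral branches
addressable by the stable labels `hominid` and `rodent`; 54 genes of 300
codons each, 30 of which form a connected random network with exactly 81
edges (a uniform spanning tree plus random extra edges, so connectedness is
guaranteed); $\kappa = 2$; uniform codon frequencies.  Each gene's true
$\omega$ is

$$\omega_g = \mathrm{clamp}\big(0.5 - 2.5\,(c_g - \bar c) + s_{f(g)} +
\varepsilon_g,\; 0.005,\; 0.95\big)$$

with $c_g$ the gene's closeness (zero contribution outside the network),
$s_f$ functional-class shifts (+0.20 retinoid-cycle enzymes, +0.18 ion
channels/exchangers, −0.20 chaperones, −0.15 G proteins, −0.08 opsins,
0 otherwise — the qualitative pattern of relaxed versus constrained classes
the analysis is designed to detect), and $\varepsilon_g \sim N(0, 0.05)$.
The clamp keeps every gene in the purifying regime ($\omega < 1$).  The
slope, shifts and noise were calibrated jointly, at the level of the true
omegas over 300 generator draws, so that the planted structure is actually
detectable at this study size — a negative closeness trend (median planted
$\rho \approx -0.64$) significant at the 5% level in over 99% of draws, and
a function-class Kruskal–Wallis effect in essentially all of them.  On a
30-node, 81-edge graph the closeness spread is narrow (SD $\approx 0.06$),
so a visually "gentle" slope would leave detection near coin-flip rates;
the calibrated slope keeps the planted regime unambiguous while the clamp
still holds every gene below $\omega = 1$.  Annotation protein
lengths are drawn independently of everything else (log-normal around the
alignment length), so the protein-length correlations are a planted null.
One global seed fans out to per-gene subseeds, making every gene
independently reproducible.

What the generator does *not* emulate: alignment error and indels (inputs
model post-cleaning data), codon usage bias (uniform $\pi$), rate variation
within genes beyond the site classes, gene gain/loss across species, and
correlated evolution between interacting genes.  Passing tests therefore
demonstrate correctness of the estimators and the statistical layer under
the stated models, not robustness to real-data pathologies such as
misalignment — which the upstream cleaning pipeline, out of scope here, is
responsible for.

## Numerical choices and degenerate inputs

* Pattern compression before likelihood evaluation; per-pattern log-scale
  tracking in both pruning passes.
* Tiny negative eigen-reconstruction round-off in $P(t)$ is clipped to zero
  and rows renormalized.
* Branch lengths are bounded in $[10^{-7}, 20]$ during optimization;
  all-at-lower-bound fits are flagged degenerate.
* Likelihood-ratio statistics are clamped at zero; a warning is emitted only
  when the deficit exceeds 0.01 log units, i.e. clearly beyond optimizer
  tolerance.
* Ties: Spearman uses average ranks; Kruskal–Wallis is tie-corrected; an
  all-tied sample reports $H = 0$ with a warning rather than NaN.
* Constant vectors make $\rho$ undefined; the battery reports them as
  missing with a warning.

## Problem sizes used in the validation suite

The acceptance-style tests run, per fixed seed set: 50 M0 recovery
simulations (500 codons), 40 site-test null calibrations (300 codons),
16 + 16 branch-site null/power replicates (300 codons), 5 BEB
discrimination replicates (600 codons), 100 random graphs for the
centrality oracle, and two full 54-gene pipeline runs.  These sizes are the
package's desk-scale choices: large enough that the binomial error bars on
the checked rates are meaningful, small enough that the whole suite runs on
one CPU in well under half an hour.  For the test-calibration and power
loops, branch lengths are fixed at each gene's M0 estimates (the common
practical shortcut for large batches); co-optimization under every model
remains the default everywhere else.

## Known limitations

* The branch-site p-value uses $\chi^2_1$, not the 50:50 point-mass mixture
  some references recommend; the statistic is reported, so either
  convention can be applied downstream.
* BEB grids are the published desk-scale design (10 points per dimension);
  posteriors for weakly informative data inherit grid granularity.
* The optimizer is local; multi-start plus warm-starting makes failures to
  order nested models rare but not impossible, and such cases are clamped
  and flagged rather than hidden.
* dN/dS inference assumes the fixed tree is correct up to the
  species-vs-gene-tree choice offered by `choose_tree()`.
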