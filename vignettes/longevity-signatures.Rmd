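---
title: "Methods: Bayesian genetic signatures of exceptional longevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian genetic signatures of exceptional longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longsig)
```

`longsig` analyses extreme-phenotype case-control cohorts — centenarians
against population controls — through a pipeline of per-SNP Bayesian
association, nested naive-Bayes classifiers, genetic risk profiles with
model-based clustering, a liability-threshold heritability solver, and a
disease-allele burden comparison. This vignette is the package's account
of those methods: the models and their assumptions, the parameters that
matter, the numerical choices, and what the synthetic cohorts used in
testing do and do not establish about real data.

## Per-SNP association model

For one SNP, genotype counts $(n_0, n_1, n_2)$ in cases and in controls
are modelled as multinomials with a conjugate Dirichlet prior
$\alpha = (1,1,1)$. The marginal likelihood of a count vector is

$$m(n;\alpha) = \frac{\Gamma(\sum\alpha)}{\Gamma(\sum\alpha + N)}
\prod_i \frac{\Gamma(\alpha_i + n_i)}{\Gamma(\alpha_i)},$$

and the Bayes factor for "the two groups have distinct genotype
distributions" against "one shared distribution" is
$BF = m(\text{case})\,m(\text{control})/m(\text{pooled})$, computed in
log space (stable for counts up to $10^6$ and beyond; `lgamma` is exact
enough that the exhaustive small-table comparison against the factorial
form agrees to $10^{-10}$). The posterior probability of association is
$BF\pi/(BF\pi + 1 - \pi)$ with $\pi = 0.5$ by default. Because the map
from $BF$ to the posterior is monotone for any fixed $\pi$, the choice of
$\pi$ never changes the SNP ranking — it only rescales the scores. The
uniform Dirichlet is a minimal-assumption choice: genotype models (e.g.
near-additive ones) could sharpen it, but would add assumptions the
ranking does not need.

Missing genotypes are excluded from the count tables SNP by SNP. No
covariate adjustment is offered: the intended design has matched
controls, and adjusting a 3-level multinomial contrast would change the
model class entirely.

**LD pruning.** Linkage disequilibrium is measured as the squared Pearson
correlation of dosage vectors over pairwise-complete subjects, defined as
0 when either vector is constant. Pruning is a single greedy pass down
the ranked list: a SNP is removed iff its $r^2$ with an already-retained
higher-ranked SNP exceeds the threshold (default 0.7 — "strong" LD is
not a standardized quantity; 0.7 is a common panel-thinning choice and it
is configurable). Ties in the ranking break on (chromosome, position,
snp_id) so output is reproducible.

## Nested classifiers and the stopping rule

The classifiers are naive Bayes: given case status, genotypes at
different SNPs are treated as independent, each with a per-class
multinomial estimated with Laplace smoothing
$P(g \mid \text{class}) = (n_g + s)/(N + 3s)$, $s = 1$ by default so no
genotype ever has probability zero in a small stratum. Model $j$ uses
exactly the first $j$ SNPs of the panel, so the family is nested by
construction; posteriors are computed as logistic transforms of
cumulative log-likelihood-ratio sums, and a subject's SNPs with missing
dosage are skipped (a subject missing the whole panel receives the class
prior, 0.5 by default to match a balanced design). These models are
equivalent to logistic scores with per-genotype weights, which is what
makes the single-number "genetic risk profile" below meaningful.

The forward search adds one panel SNP at a time and tracks balanced
performance, $(\text{sensitivity} + \text{specificity})/2$, under
stratified 5-fold cross-validation with a seeded fold assignment
(resubstitution is available for comparison). "Stopped improving" is
operationalized as: no improvement of more than $\varepsilon = 0.001$
over the best value seen, for 10 consecutive additions (the patience).
The selected size $k_\max$ is the argmax of balanced performance over the
explored prefix. The tolerance and patience are deliberately loose-grained:
at cohort sizes in the low thousands, balanced-performance increments
below $10^{-3}$ are far inside fold noise.

Prediction uses the unweighted mean of the $k_\max$ nested posteriors
(the ensemble); it is bounded by the extreme single-model posteriors and
is less sensitive to false-positive SNPs admitted late in the panel than
the largest model alone.

**An honesty caveat that shaped the tests.** The panel is ranked on the
full cohort before the forward search cross-validates model *size*. On
null data this leaks selection signal: the top-ranked of 1,000 null SNPs
are (by selection) case-control-discrepant in-sample, and within-sample
CV of the size still reports balanced performance near 0.57 on 2,000
subjects. The package therefore treats held-out evaluation as the honest
performance measure: the no-signal control in the test suite fits the
whole pipeline (association, pruning, forward search) on half of a null
cohort of 2,000 subjects by 1,000 SNPs and evaluates the ensemble on the
other half, giving balanced performance within $0.5 \pm 0.05$. Users
reporting sensitivity/specificity from `longevity_model()` on the
training cohort should expect the same optimism.

## Risk profiles and signature clustering

Subject $s$'s genetic risk profile is the curve
$p_j(s) = P(\text{case} \mid \text{first } j \text{ SNPs of } s)$,
$j = 1..k_\max$. Two subjects with similar profiles carry similar
longevity-associated genotype patterns even if not identical alleles.

Profiles are clustered agglomeratively under a Bayesian product-Gaussian
model: within a cluster, each profile coordinate is
$x \sim N(\mu_d, \sigma_d^2)$ with a conjugate normal-inverse-gamma prior
($\mu_0 = 0.5$, the midpoint of a probability scale; prior strength
$\kappa_0 = 1$ pseudo-observation; variance prior shape 1, scale 0.01 —
a weak prior guess that profile coordinates vary on the $\sim 0.1$
scale). The marginal likelihood of a cluster is closed-form, so each
candidate merge has an exact Bayes factor (one component versus two).
Starting from singletons, the best-scoring merge is applied while its
Bayes factor is at least `min_bf` (default 1; `Inf` recovers all
singletons), ties breaking on the lowest pair of cluster indices. The
method this adapts was formulated for clustering dynamics; the static
adaptation here replaces its Markov-chain likelihood with the
per-coordinate Gaussian, keeping the agglomerative
marginal-likelihood-ratio search. Because merges are only applied at
$BF \ge 1$, the total log marginal likelihood never decreases along the
merge trace. The clustering depends on the data only through per-cluster
sufficient statistics, so it is permutation-equivariant up to the
tie-break.

Signature-phenotype association uses a permutation test on the
between-cluster variance of mean ranks (the Kruskal–Wallis numerator) —
rank-based because onset ages and ordinal survival classes are neither
normal nor on a shared scale — with the p-value computed as
$(1 + \#\{T^{perm} \ge T^{obs}\})/(N+1)$.

## Liability-threshold heritability

Prevalence $K$ fixes the threshold $T = \Phi^{-1}(1-K)$ on a
standard-normal liability; relative pairs share liability with
correlation $\rho = a h^2$, $a = 1/2$ for full siblings under purely
additive genetics (no shared environment — the assumption to question
first if the numbers look too large). Then

$$\lambda_R = \frac{P(L_1 > T, L_2 > T;\ \rho)}{K^2},$$

and the solver inverts $\lambda_R \mapsto h^2$ by `uniroot` on $[0,1]$
(the map is strictly increasing), with the bivariate-normal upper tail
reduced to a one-dimensional integral
$\int_T^\infty \phi(x)\,\bar\Phi\!\big((T-\rho x)/\sqrt{1-\rho^2}\big)\,dx$
evaluated adaptively to well below $10^{-10}$ absolute error. The tail
reduction is cross-checked in the tests against Sheppard's closed form at
$T = 0$ ($1/4 + \arcsin\rho/2\pi$) and an independent two-dimensional
quadrature; the round trip $h^2 \to \lambda \to h^2$ reproduces inputs to
$10^{-6}$ over $K \in \{10^{-4},10^{-3},10^{-2}\}$. A $\lambda_R$ above
the $h^2 = 1$ bound is rejected with the bound in the message.

With the centenarian prevalence $K = 1/5000$ and sibling relative risks
8 and 17 (female and male strata), the solver returns $h^2 = 0.333$ and
$0.479$. Sex-specific prevalences can be substituted via the `prevalence`
argument; with the plain $1/5000$ both published values are reproduced,
so no such substitution is needed.

## Disease-allele burden

The catalog maps SNP ids to a risk allele base and a disease group.
After intersecting with the genotype panel (entries whose risk allele
matches neither the reference nor the alternate allele — e.g. strand
flips — are flagged and dropped), each subject's burden in a group is
the risk-allele dosage summed over the group's SNPs divided by the
number of non-missing SNPs, a rate in $[0, 2]$ invariant to consistent
ref/alt flips. Group means are compared case versus control by a seeded
two-sided permutation test on the mean difference; groups are reported
without multiplicity adjustment (they are separate hypotheses presented
stratified), with a Bonferroni column for reference.

## The synthetic cohort generator

The generator exists so every stage can be exercised against planted
truth. It emulates:

* **Hardy–Weinberg genotypes** at MAFs drawn uniformly from a range
  (default 0.05–0.5);
* **block LD** via a latent exchangeable Gaussian copula within blocks
  (default size 10, correlation 0.3) thresholded at the HWE genotype
  quantiles — this controls marginal MAF exactly while inducing
  within-block dosage correlation;
* **case ascertainment** by rejection sampling: a candidate with causal
  dosages $g$ becomes a case of class $r$ with probability
  $\mathrm{logit}^{-1}\!\big(\mathrm{logit}(\pi_0) + \beta_r
  \sum_j (g_j - 2p_j)\big)$, with
  $\beta_r = \beta \cdot m^{r-1}$ (defaults $\beta = 0.3$, $m = 1.5$, 40
  causal SNPs among 2,000; cohort 1,000 controls and 300/150/50 cases in
  classes 100–104, 105–109, 110+). The baseline probability
  $\pi_0 = 0.01$ matters: the phenotype is rare, so the logistic
  intercept sits far below zero and selection behaves like exponential
  tilting, turning per-allele log-odds into real allele-frequency shifts
  that grow with the class. With an intercept at zero the acceptance
  probability saturates and classes beyond the first become almost
  indistinguishable — a regime worth knowing about when choosing effect
  sizes: once the standard deviation of the total causal load approaches
  $|\mathrm{logit}(\pi_0)|$, further load stops shifting frequencies.
  The graded-sensitivity checks in the test suite therefore plant 15
  causal SNPs at $\beta = 0.35$, $m = 1.5$, squarely in the informative
  regime.

Controls are population samples (not screened non-cases), so null SNPs
are exactly HWE-distributed in every class; with no planted effects the
whole cohort is exchangeable. The recorded truth includes the causal ids,
per-class betas, and a single-SNP approximation to the expected causal
allele frequency per class (exact computation would integrate over the
load of the other causal SNPs; the approximation is used only for
qualitative ordering checks).

What the generator does **not** emulate: realistic human LD maps,
population structure or ancestry mismatch between cases and controls,
genotyping batch effects, age-at-death processes, or linked causal
variants tagging each other. Passing recovery tests on these cohorts
shows the machinery is correct and calibrated under its own model — not
that a real cohort of the same size would yield panels of the same
quality.

The profile fixture generator plants monotone nondecreasing cluster mean
curves (level-scaled ramps topping out at 0.95) separated by a chosen
sup-norm gap, plus truncated Gaussian noise clipped to $[0,1]$; at
separation 0.5 at most two such curves fit in the unit interval, which is
what the clustering recovery tests use (adjusted Rand index $\ge 0.95$
at noise 0.05).

## Problem sizes and runtime

The test suite runs end-to-end in well under a minute: the largest
fixtures are the 2,000-subject null cohort (1,000 SNPs) for the
no-signal control, the default cohort (1,500 subjects, 2,000 SNPs) for
rank-recovery, and a 2,000-subject graded cohort (600 SNPs) for the
class-sensitivity check. These sizes were chosen to keep Monte-Carlo
noise comfortably inside the tested tolerances while staying
seconds-scale; the algorithms themselves are vectorized (count tables by
column sums, posteriors by cumulative log-likelihood ratios, LD by one
correlation-matrix evaluation) and scale to panels in the tens of
thousands of SNPs on a single core.

## Known limitations

* Naive Bayes ignores inter-SNP dependence beyond what pruning removes;
  residual LD inside the panel double-counts evidence and pushes
  posteriors toward 0/1. The ensemble softens but does not remove this.
* The stopping rule explores a prefix; a signal SNP ranked far below a
  long noise plateau (beyond the patience) will be missed.
* The clustering Bayes factor assumes coordinate independence within a
  cluster; profiles are cumulative products and strongly autocorrelated,
  so cluster counts should be read as resolution-dependent descriptions,
  not as an estimate of a true number of subpopulations.
* The heritability solver inherits every liability-threshold assumption:
  normal liability, purely additive familial resemblance, no shared
  environment, exact prevalence. Its outputs are as soft as those inputs.
* Genotype QC (call-rate filters, HWE tests in controls) is deliberately
  out of scope; upstream tools do this better, and the readers accept
  whatever passes their validation rules.
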