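---
title: "Methods: genome-face linkage risk and the perturbation defense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-face linkage risk and the perturbation defense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolink)
```

## The threat model

phenolink quantifies a linkage (re-identification) attack: an adversary
holds a collection of genomic records and a face image, and asks which
record belongs to the person in the image. The bridge between the two data
types is a small set of phenotypes visible in a photograph — sex, hair
colour, skin colour and eye colour — each informed by a handful of SNPs.

The attack has three parts:

1. **Phenotype prediction from pixels.** One classifier per phenotype maps
   an image $x_i$ to a probability distribution $g_p(\cdot, x_i)$ over that
   phenotype's variant domain; the most likely variant is $z_{i,p}$.
2. **Phenotype probability given a genome.** For each phenotype $p$ and
   variant $v$, $P(v \mid y_j)$ is a naive-Bayes product over the
   phenotype's relevant SNPs of empirical conditionals
   $P(v \mid \text{genotype at that SNP})$, estimated from a fitting cohort
   by counting with additive smoothing
   $\hat P(v \mid g) = (n_{v,g} + \alpha)/(n_g + \alpha |D_p|)$.
3. **The matching score.** Every image-genome pair receives
   $$p_{ij} = \sum_{p \in \{\text{sex, hair, skin, eye}\}} \log P(z_{i,p} \mid y_j),$$
   computed in log space for numerical stability, with each probability
   floored at `prob_floor` ($10^{-12}$) before the log so scores stay
   finite even with unsmoothed tables.

Risk is then evaluated two ways: the fraction of images whose true genome
ranks in the attacker's top $k$, swept over the population size of the
genome gallery; and a pooled ROC/AUC treating every pair as a binary
match/non-match decision, thresholded either on the rank $k$ or on a score
cutoff $\tau$. Two baselines bracket the attack: random assignment (success
$k/N$) and matching with the individuals' *actual* phenotypes, which is the
ceiling for any image-based attacker that observes these four traits.

## Estimation choices

* **Smoothing** ($\alpha = 1$ by default, configurable). Raw empirical
  frequencies produce $P = 0$ cells and hence $\log 0$; a pseudo-count is
  the minimal fix and its bias ($\mathcal{O}(1/n_g)$) is negligible at the
  fitting sizes used here. Genotypes never seen in fitting are served the
  uniform distribution rather than an error: at attack time an unseen
  genotype carries no information.
* **Missing genotypes** contribute a neutral factor of 1 to the product
  (they are skipped), matching the product-over-relevant-SNPs formulation
  without inventing an imputation model; a uniform-factor alternative is
  available (`missing_policy = "uniform"`). Missingness is explicit (`NA` /
  `--`), never silently dropped.
* **Genotype canonicalisation.** Allele pairs are stored sorted ("AG" ≡
  "GA"); inputs are assumed to be reported on a consistent strand.
* **No renormalisation** of $P(\cdot \mid y)$ across variants by default:
  the score uses raw products. A normalised mode exists for diagnostics
  only.
* **Ties in top-**$k$ are broken deterministically by genome list order;
  an expected-success mode under uniformly random tie-breaking is also
  provided. Real-valued scores make ties rare, but heavily smoothed toy
  tables do produce them, and an unspecified tie rule would make results
  irreproducible.
* **Population sweeps** subsample, for each population size $s$, a
  subpopulation of $s$ individuals and match their images against exactly
  those $s$ genomes, so each probe's true genome is always present (the
  attack is evaluated under the assumption that a match exists).
  Subsampling is independent across sizes and replicates and fully
  seeded.
* **AUC** is the trapezoidal integral over the unique-threshold ROC points;
  pairs are pooled across images by default with a per-image macro-average
  behind a flag. Natural logarithms are used throughout (the base does not
  affect rankings).

## The synthetic cohort

No paired genome-image data can be distributed, so the package generates
cohorts with *known* generating distributions; every experiment in the test
suite and the acceptance script runs on them.

* **Genotypes**: biallelic SNPs (2-4 per phenotype in the default panel)
  drawn under Hardy-Weinberg equilibrium from per-SNP allele frequencies
  (default 0.5, strictly inside $(0,1)$).
* **Phenotypes**: sampled from the product of the per-SNP generating
  conditionals, renormalised — the same combination rule the scorer
  assumes, which makes parameter recovery well-posed: fitting conditionals
  on a generated cohort must converge to the generating tables. A
  deliberately misspecified per-SNP-voting rule (`combine = "vote"`) exists
  for robustness experiments. Generating tables peak at 0.85 on a
  dosage-ordered variant, a strength typical of the strongly informative
  pigmentation SNPs this panel emulates.
* **Images**: deterministic 32×32 RGB "faces" on a fixed base colour. Each
  phenotype variant raises one colour channel by a contrast of 0.06 inside
  its region (hair band, eye patch, skin strip/background), and sex is a
  low-contrast shape cue (vertical bar for M, horizontal for F); seeded
  Gaussian noise (sd 0.05 by default) is added and pixels are clipped to
  $[0,1]$. The small contrast is deliberate: phenotype evidence in real
  photographs is subtle, and perturbation experiments are only meaningful
  when an $\ell_\infty$ budget in the studied range (0.001-0.05) is
  commensurate with the signal a classifier reads. For a linear classifier
  a prediction flip requires roughly $\epsilon \gtrsim$ contrast/2, so the
  0.06 encoding places the flip threshold inside the studied grid —
  saturated patch colours (contrast ~0.5) would make every classifier
  trivially robust and the defense unexercisable at any realistic budget. A
  rule-based decoder (region means, nearest offset) recovers phenotypes
  exactly at zero noise, verifying the encoding.
* **Classifier-error simulator**: `simulate_noisy_predictions()` bypasses
  images entirely, emitting argmax-correct predictions with probability
  $1 - \text{confusion}$ and a uniform wrong variant otherwise — useful for
  fast matching experiments and for emulating hard phenotypes (the
  real-world analogue being eye colour, which is both hard to predict and
  influential in matching).

What passing tests on these cohorts do **not** show: performance on real
photographs (pose, lighting, occlusion, dyed hair, contact lenses), real
linkage disequilibrium between SNPs, population structure, or the
calibration of any particular deep classifier. The generator emulates the
*structure* of the problem — genotype-conditional phenotypes observable
through a noisy channel — not its photographic surface.

## The reference classifiers

The classifier contract required by the defense is small: softmax outputs
per phenotype plus gradients of any scalar function of the logits with
respect to the input pixels (`clf_predict` / `clf_input_grad`). The
reference implementation is a per-phenotype multinomial logistic (linear
softmax) model on flattened pixels, trained by full-batch cross-entropy
descent with adaptive first/second-moment (Adam-style) steps, seeded and
exactly reproducible. A linear model is sufficient here — the synthetic
images are linearly separable by construction and the models reach ≥95%
held-out accuracy at zero render noise — and its gradients are exact and
hand-verifiable, which matters because every downstream result flows
through those gradients. The training default is 300 full-batch iterations
(convergence of the slowest, three-class classifiers). Per-class loss
weighting is exposed as a flag rather than hard-coded. Any differentiable
model, including a fine-tuned deep face network wrapped to expose the same
two methods, can be plugged in unchanged.

## The perturbation defense

The defender minimises the matching score between an image and its *true*
genome. The score depends on classifiers only through the discontinuous
argmax, so the optimised surrogate couples predicted probabilities to
genome conditionals:
$$\min_{-\epsilon \le \delta \le \epsilon}
  \sum_p \sum_{v_p} \log g_p(v_p, x_i + \delta)\, \log P(v_p \mid y_j).$$
Both factors are negative; the objective decreases as prediction mass moves
toward variants improbable under the true genome. This double-log form is
the default (`form = "log_log"`), implemented literally. Because an
expected-log-likelihood reading
$\sum_p \sum_v g_p(v_p, x+\delta) \log P(v_p \mid y_j)$ is also defensible,
it is provided behind `form = "expected_loglik"` rather than silently
chosen.

Optimisation is projected gradient descent: adaptive-moment gradient steps
on $\delta$, then after every step the noise is clipped to
$[-\epsilon, \epsilon]$ and the perturbed pixels to $[0,1]$. The starting
point is the original image ($\delta = 0$; random starts in the box are
used during adversarial training). Defaults: 100 steps, step size
$\epsilon/10$ — the iteration budget is not prescribed anywhere, so it was
set where traces visibly plateau on the synthetic worlds. The *best*
iterate by objective is returned, making "final ≤ initial" unconditional.
Inside the objective, $g$ is floored at $10^{-20}$: trained softmax outputs
underflow, and an unfloored log would make the reported objective
infinite. The gradient is that of the unfloored objective (exact for the
softmax), so progress continues through the floored region even while the
reported value is flat.

The single-phenotype baseline (`targeted_phenotype_perturbation`) is the
conventional misclassification attack — PGD pushing one classifier away
from its current argmax under the same projections — and is consistently
weaker at suppressing the true-pair score than the tailored objective,
since misclassifying one trait need not break the match.

## Adversarial training

To ask whether an attacker can neutralise the defense, the ensemble is
hardened by iterated retraining: in each of five passes (the default),
perturbations are regenerated against the *current* model from random
starting points in the $\epsilon$ box, and one training epoch runs on the
perturbed inputs in place of the originals (a mix-ratio flag blends clean
inputs back in; the exact augmentation ratio is a free choice and replace
is the cleanest default). Perturbations are generated from the defense
objective by default — the attack being countered targets the matching
score, not the individual classifiers — with per-classifier cross-entropy
perturbations behind a flag. Paired genome-image data are therefore
required; the default split is 60% train / 40% test. Evaluation defends the
held-out images at a grid of budgets against the hardened model and
reports top-$k$ success, alongside the clean model under the same attack.

Two qualitative behaviours define success here and are asserted on means
across seeds: the hardened model retains more matching success under
attack at its training budget than the clean model, and pays for it with
lower clean-input matching success.

## Problem sizes and numerical conventions

The reference experiments use cohorts of 12-40 individuals (40 for defense
and robustness studies, matching the scale at which the random baseline
$1/N$ is still measurable with 40 probes), 32×32×3 images, 300 training
iterations, 40-60 PGD steps, and 5-10 seed replicates for directional
claims; the random-matching null uses 10,000 synthetic score matrices.
These sizes make every stochastic assertion testable with explicit
standard-error bounds while each experiment stays in the seconds-to-minutes
range on one CPU. All randomness flows from a single master seed through
named substreams (`derive_seed(master, label)`), so adding a stage never
shifts another stage's stream, and identical configurations reproduce
byte-identical reports.

## Known limitations

* The default SNP panel is synthetic; real trait-informative panels (and
  their linkage structure) must be supplied by the user as a schema.
* The naive-Bayes conditionals assume independence across a phenotype's
  SNPs; real pigmentation loci violate this.
* The linear reference classifiers quantify the *mechanics* of the attack
  and defense, not the accuracy of any particular deep model; their
  robustness geometry (flip threshold ≈ margin) is simpler than a deep
  network's.
* Open-set matching (no true genome present) and score calibration to
  posterior match probabilities are out of scope; success rates here
  assume the match is in the gallery and are therefore upper bounds in
  that respect.
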