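---
title: "Modelling bulk RNA-seq with a deep generative decoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bulk RNA-seq with a deep generative decoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dgdr` fits a decoder-only generative model of raw bulk RNA-seq counts.
Every sample $i$ owns a free latent vector $z_i \in \mathbb{R}^D$ (its
*representation*); there is no encoder. A feed-forward decoder
$f_\theta$ with rectified hidden layers and a rectified output maps $z_i$
to per-gene relative expression, which is scaled by the sample's mean
count $s_i$ (its *sample scale*) and floored at $\varepsilon > 0$:

$$ m_{ig} = \max(0, f_\theta(z_i)_g)\, s_i + \varepsilon . $$

Counts are negative binomial,
$$ NB(k; m, r) = \frac{\Gamma(k+r)}{k!\,\Gamma(r)}
   \Big(\frac{r}{r+m}\Big)^{r} \Big(\frac{m}{r+m}\Big)^{k}, $$
with a gene-specific dispersion $r_g$ (variance $m + m^2/r$) shared
across samples. The latent space carries a Gaussian mixture
$p(z) = \sum_c w_c\, N(z; \mu_c, \mathrm{diag}(e^{-\beta_c}))$, which both
regularizes the representations and provides an unsupervised tissue
clustering through hard component assignment.

Priors are placed on the mixture parameters themselves: a *softball*
prior on each $\mu_c$ — a uniform ball of radius `spread` whose boundary
is mollified by a logistic of steepness `sharpness` — a Gaussian
(mean 1, sd 1) on each entry of $\beta$ (the *negative natural log* of a
diagonal variance), and a symmetric Dirichlet ($\alpha = 5$) on $w$.
Everything — representations, decoder, dispersions, mixture — is learned
jointly by maximizing the penalized log joint
$$ \sum_i \Big[ \sum_g \log NB(x_{ig}; m_{ig}, r_g) + \log p(z_i) \Big]
   + \log p(\mu, \beta, w) . $$

### Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `latent_dim` | 50 | representation dimension $D$ |
| `n_components` | 45 | mixture components $C$ |
| `hidden` | 500, 8000 | decoder hidden widths |
| `dispersion_init` | 2 | starting NB dispersion per gene |
| `spread`, `sharpness` | 7, 10 | softball radius / boundary steepness |
| `beta_mean`, `beta_sd` | 1, 1 | Gaussian prior on $\beta_{cd}$ |
| `alpha` | 5 | Dirichlet concentration on weights |
| `epochs`, `batch_size` | 200, 256 | training schedule |
| learning rates | 1e-4 / 0.01 / 0.01 / 0.01 | decoder / representations / mixture / dispersions |
| Adam betas | 0.5, 0.9 | moment decay |

The defaults describe the full-scale model of a multi-tissue compendium
(tens of thousands of samples, ~17k genes). For smaller studies the
geometry-dependent hyperparameters should scale with the problem; see
"Reduced models" below.

A note on $\beta$: the prior is a Gaussian with mean 1 on the negative
natural log variance, giving a per-dimension prior-mode standard
deviation of $e^{-1/2} \approx 0.61$. Both the prior mean and sd are
exposed; no other log base is used anywhere.

## Training mechanics

Each parameter group — decoder weights, representations, mixture
parameters, dispersions — has its own Adam instance. Representations are
updated once per epoch: every sample appears in exactly one shuffled
minibatch. The per-batch objective is the negative batch-mean of the
per-sample log joint, minus the mixture parameter log prior divided by
the number of batches, so a full epoch applies the prior with total
weight one regardless of batch size.

Choices the published recipe leaves open, fixed here:

* **Dispersion optimizer.** The three named optimizers cover the
  decoder, representations and mixture. Gene dispersions are
  distribution parameters like the mixture's, not network weights, so
  they receive their own Adam instance at the distribution-parameter
  rate (0.01 by default) rather than the decoder's 1e-4. On short
  schedules a rate tied to the decoder would freeze dispersions at their
  initial value, and the single-sample test would inherit a mis-specified
  variance for every gene.
* **Initialization.** Representations start at zero (as specified);
  decoder weights use fan-in uniform draws; all decoder biases start
  positive (hidden 0.5, output 1) so every rectified unit is active at
  the zero representation — a unit that starts dead receives no gradient
  ever, and with $z = 0$ the output otherwise predicts each gene at the
  sample mean, a sensible origin. Mixture means are drawn uniformly
  inside the softball support; weights start uniform.
* **$\beta$ initialization.** Components start *narrower* than the prior
  mode ($\beta_{init} = \beta_{mean} + 1.5$). Wide components let the
  first component that reaches the data capture several nascent
  clusters; narrow ones keep early responsibility competition local.
* **Gradient clipping.** The NB gradient with respect to a decoded mean
  is \eqn{k/m - (k+r)/(r+m)}, which explodes as a rectified output
  approaches zero under a positive observed count. A single such spike
  inflates Adam's second-moment estimates and stalls learning for many
  subsequent steps; unchecked, it caps the decoder's attainable
  accuracy. The reconstruction gradient is therefore clipped
  elementwise (`grad_clip`).
* **Dead-output rescue.** A gene whose rectified output is exactly zero
  for samples with positive counts receives no gradient through the
  ReLU mask and can never recover; every `revive_every` epochs such
  genes get a small output-bias bump that re-opens the gradient path.
  A gene that truly is silent there is pushed back down by the restored
  gradient.
* **Idle/redundant-component revival.** Joint gradient fitting of a
  mixture over a slowly moving point cloud has the same local optima as
  k-means/EM: a component can cover two clusters while spares sit
  stacked on a third. Every `revive_every` epochs (during the first
  70% of training) a component whose responsibility-mass share falls
  below `revive_share / C` is reseeded at the representation the
  mixture currently explains worst, with covariance and Adam state
  reset — the classical empty-cluster device. `revive_every = 0`
  disables both this and the dead-output rescue.
* **Component consolidation.** After the last epoch, component pairs
  whose means sit within `consolidate` pooled standard deviations are
  moment-matched and collapsed onto identical parameters (weights split
  evenly): a population described twice is described once, which makes
  hard assignments consistent while leaving the mixture density
  essentially unchanged. This is standard mixture reduction.
* **Dispersion refit.** After training, each gene's dispersion is
  re-estimated by profile maximum likelihood at the fitted means.
  Gradient updates shape the dispersions during training but cannot
  traverse the full biological range within a short schedule; the refit
  is likelihood-optimal given the decoder actually obtained. It also
  self-calibrates: where the decoder fits a gene poorly the refit
  lowers \eqn{\hat r}, widening that gene's NB and making the
  single-sample test conservative exactly where the model is weak.

Reproducibility: with a fixed `seed`, initialization, batch shuffling,
and therefore the entire loss history and all parameters are
bit-reproducible.

## Closest-normal inference

For an unseen sample, all model parameters are frozen and only a new
representation is optimized. One candidate starts at each component
mean; each gets `search_epochs` (10) Adam steps on the log joint; the
best candidate by the objective is refined for `refine_epochs` (50) more
steps. Selection uses the *joint* objective (reconstruction + mixture
density) by default; `objective = "reconstruction"` switches both search
and selection to the likelihood alone. If refinement ends below the
selected candidate's objective (beyond 1e-6) the pre-refinement vector
is restored, so refinement can never make the answer worse. Samples are
processed independently; their order cannot affect any result.

The inferred vector is the model's *in-silico control*: the point in
the healthy-expression manifold closest to the query. Its decoded NB
distributions parameterize the single-sample test, and the total
negative log probability mass $-\sum_g \log NB(x_g; m_g, r_g)$ ranks
samples by how far outside the training distribution they fall.

### The query's library scale

Training samples use the arithmetic mean count as their scale, and the
relative profiles are normalized so this is consistent. For a *query*,
the mean is contaminated by the very effects being tested: with a few
hundred genes, twenty genes spiked fourfold inflate the mean by tens of
percent, which both biases every reference mean upward and shrinks the
apparent fold change of the spiked genes themselves. By default
(`scale_method = "robust"`) inference therefore refines the initial
mean-count scale into a median-of-ratios size factor against the
decoded relative profile — the same robustness idea as standard
count-model size factors — and re-refines the representation at that
scale. `scale_method = "mean"` recovers the plain convention; the two
agree for in-distribution samples.

## The single-sample test

For each gene the observed count $x$ is compared against $NB(m, r)$ at
the inferred representation. The two-tailed p-value is the total
probability of all counts no more probable than $x$:
$$ p = \sum_{k=0}^{K} NB(k; m, r)\,
   I[NB(k; m, r) \le NB(x; m, r)], $$
with $K$ the library size. Ties are included and $x$ itself always
contributes, so $p \in (0, 1]$ and the test is conservative on a
discrete support. Because the NB pmf is unimodal, the strict
super-level set $\{k : NB(k) > NB(x)\}$ is one contiguous run; the
implementation finds its two boundaries by binary search and takes CDF
differences, which reproduces the literal sum in $O(\log K)$ time at
any library size (the suite checks equality against brute-force
summation at $10^{-12}$).

The grid variant evaluates the pmf only on an evenly spaced integer
grid (default $10^4$ points over $[0, K]$), brackets the same two
boundaries, and refines them by fitting the NB log pmf's own form
$\alpha + \beta k + \gamma \log(k+1)$ through the bracketing nodes. The
error is purely boundary-location error; it vanishes as the grid
refines, and a saturated grid returns the exact value. When the entire
distribution sits inside a single grid cell the cell is summed exactly
instead (no more evaluations than the grid itself would use); a grid
that covers a narrow distribution with only 2–3 cells remains a crude
approximation, which is why `dgd_test()` defaults to the exact test.

Fold changes are $\log_2((x + 1)/(m + 1))$; the pseudocount keeps zeros
finite and is exposed. Adjustment is Benjamini–Hochberg by default
(Bonferroni by flag), and a gene is called at `padj < 0.01` and
`|log2FC| > 1`. The enrichment score of a marker set is the marker
fraction among called genes over the marker fraction in the universe.

## The synthetic cohort generator

`simulate_cohort()` provides ground truth for validation: tissue
archetypes placed on scaled coordinate axes exactly `separation` apart
(default 6), isotropic latent noise (`noise_sd` 0.5), a random
linear-plus-rectifier truth decoder whose relative profiles are
normalized to mean 1 per sample (so the library scale is identifiable
as the sample's mean count, matching the model's convention), log-normal
library scales (median 200 counts/gene), and gene dispersions drawn
log-uniformly over [0.5, 20] to span the regimes the NB test must
handle. The truth decoder is deliberately *not* a deep network: means
are hand-computable, so tests can compare against closed-form truth.

The generator emulates the statistical skeleton the model assumes —
clustered latents, NB counts, sample-specific depth. It does not
emulate batch effects, GC or length bias, cell-type composition
gradients, or correlated gene modules; passing recovery tests on it
shows the estimator works where its assumptions hold, not that those
assumptions hold in any given real dataset.

### Spike-in panels

`spike_sample()` redraws chosen genes from the NB at a fold-changed
mean, leaving all other genes bit-identical — a positive control with
known differential genes. A single-observation NB test has limited
power at moderate dispersion: the NB standard deviation is roughly
$m/\sqrt{r}$ for well-expressed genes, so a four-fold up-shift sits
within about two standard deviations of the mean for $r \lesssim 4$
and only becomes reliably detectable at the multiple-testing threshold
once $r$ reaches about 8; down-shifts are weaker still because the
lower tail is bounded at zero. The default panel therefore draws
up-regulated spikes among genes with above-median expression and
$r \ge 8$ (topping up from the most expressed low-noise genes if a
draw leaves too few) — the regime where a four-fold change exceeds
single-sample noise, which is also how real marker panels are chosen
(robustly expressed, low-noise genes). Panels outside that regime are
a power study, not a pipeline check, and can be requested explicitly.

## Reduced models

The validation study used in the test suite and acceptance script is a
five-tissue cohort (100 training and 20 held-out samples per tissue,
200 genes) fitted with a reduced architecture: $D = 5$, $C = 8$, hidden
layers 32/64, 150 epochs. Hyperparameters that encode geometry or
per-step budgets are scaled with it, as they must be:

* `spread` 3: representation norms scale like
  $\sqrt{D} \times$ (per-coordinate movement), so the full-scale radius
  7 (matched to $D = 50$) is far outside the reachable region at
  $D = 5$; mixture means initialized there would never meet the data.
* batch size 32 and decoder rate 5e-4 with `grad_clip = 10`: with 500
  samples and 150 epochs the decoder takes ~2400 steps; at the
  full-scale rate (1e-4) the weights could barely move over the
  schedule, while much faster rates let the decoder absorb the latent
  scale so quickly that the representations collapse into a region the
  mixture cannot resolve. Representations use 0.03, dispersions 1e-3,
  mixture 0.05, for the same per-step-budget reason.
* inference rate 0.05: the fixed 10-step search and 50-step refinement
  must actually converge; at the full-scale default (0.01) a query
  sitting at the edge of its tissue's cluster cannot be reached within
  the step budget, and the residual decode error shows up as false
  positive calls. The overshoot guard makes the larger rate safe.

These sizes keep the complete suite and the acceptance script well
inside desktop time on one CPU while leaving every qualitative property
of the full model intact.

## Known limitations

* Tissues with genuinely similar expression can share a component, as
  multi-subtype tissues do at full scale; hard assignment then
  under-reports matching even when the representation geometry is
  correct.
* The dispersion estimate absorbs decoder misfit; this keeps the test
  calibrated (conservative) but means $\hat r$ is not a clean estimate
  of biological dispersion.
* The single-sample test has low power against modest fold changes in
  highly dispersed genes — an information limit of N-of-one designs,
  not an implementation artifact.
* Inference candidates start at component means; a query unlike
  anything in training falls back to the least-bad mode rather than
  extrapolating.
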