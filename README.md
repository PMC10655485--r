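# dgdr — deep generative decoder models of bulk RNA-seq

Differential expression analysis normally needs control samples, and bad
controls are the main source of irreproducible gene lists: adjacent
normal tissue carries disease traits, cohorts of other individuals carry
genetic heterogeneity, and single-patient ("N-of-one") settings have no
controls at all. `dgdr` implements the alternative: learn a generative
model of *normal* expression once, then let the model supply the control.

The model is a deep generative decoder (DGD). Every sample $i$ owns a
free latent representation $z_i \in \mathbb{R}^D$ (no encoder); a
rectified feed-forward decoder $f_\theta$ maps it to per-gene relative
expression, scaled by the sample's mean count $s_i$, giving a negative
binomial for every gene:

$$ x_{ig} \sim NB\big(m_{ig},\, r_g\big), \qquad
   m_{ig} = \max(0, f_\theta(z_i)_g)\, s_i + \varepsilon, $$

$$ NB(k; m, r) = \frac{\Gamma(k+r)}{k!\,\Gamma(r)}
   \Big(\frac{r}{r+m}\Big)^{r} \Big(\frac{m}{r+m}\Big)^{k}, $$

with gene-specific dispersion $r_g$. A Gaussian mixture
$p(z) = \sum_c w_c N(z; \mu_c, \mathrm{diag}(e^{-\beta_c}))$
parameterizes the latent space (softball prior on the means, Gaussian
prior on $\beta$, Dirichlet on $w$); its components cluster tissues
without supervision. Representations, decoder, dispersions and mixture
are learned jointly by penalized maximum likelihood with one Adam
instance per parameter group.

For a new (e.g. tumor) sample, the model parameters are frozen and the
representation that maximizes the sample's probability is inferred —
the *closest normal*, an in-silico control informed by the whole
training compendium. Each gene is then tested against its NB with the
exact two-tailed count-level p-value

$$ p \;=\; \sum_{k=0}^{K} NB(k; m_g, r_g)\;
   I\big[NB(k; m_g, r_g) \le NB(x_g; m_g, r_g)\big], $$

($K$ = library size; a $10^4$-point grid approximation is available),
followed by BH adjustment, $|\log_2 FC| > 1$ filtering, and
marker-enrichment scoring.

## Worked example

```r
library(dgdr)

# a five-tissue synthetic cohort with known ground truth
sim <- simulate_cohort(n_tissues = 5, genes = 200, samples_per_tissue = 100,
                       seed = 11)

fit <- dgd(sim$counts, tissues = sim$truth$tissue,
           latent_dim = 5, n_components = 8, hidden = c(32, 64),
           prior = dgd_prior(spread = 3),
           control = dgd_control(epochs = 150, batch_size = 32,
                                 lr_decoder = 5e-4, lr_representation = 0.03,
                                 lr_gmm = 0.05, lr_dispersion = 1e-3,
                                 grad_clip = 10),
           seed = 1)
fit
#> Deep generative decoder (fitted)
#>   genes: 200   latent dim: 5   mixture components: 8
#>   decoder: 5 -> 32 -> 64 -> 200 (rectified)
#>   samples: 500
#>   final loss: 1135.0978 (epoch 150)

# unsupervised tissue clustering via hard component assignment
comp <- assign_component(fit$representations, fit$gmm)
assoc <- association_matrix(comp, sim$truth$tissue)
round(assoc$percent["tissue1", ], 1)
#>   1   2   4   6   8
#>   0   0   0   0 100

# single-sample DE: spike 20 genes four-fold in one sample, then test it
sp <- spike_sample(sim$counts[500, ], sim$truth, 500, n_genes = 20,
                   fold = 4, seed = 2)
de <- dgd_test(fit, sp$counts, lr = 0.05)  # infers the closest normal itself
sum(de$called)                           # genes called (padj<0.01, |lfc|>1)
#> [1] 19
mean(sp$genes %in% de$gene_id[de$called])  # recovery of the spiked panel
#> [1] 0.95
```

The printed numbers above are the output of this exact script at these
seeds. `summary(fit)` reports loss terms, component occupancy and the
tissue-component association matrix; `plot(fit)` draws the latent PCA.

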