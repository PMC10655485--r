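#' Simulate a multi-tissue bulk RNA-seq cohort with known ground truth
#'
#' Generates count cohorts with the statistical structure the model
#' assumes, so every stage of the pipeline can be validated against known
#' truth: tissue archetypes in a latent space, per-sample latent vectors
#' (archetype plus isotropic noise) pushed through a linear-plus-rectifier
#' truth decoder into per-gene relative expression normalized to mean 1,
#' a log-normal per-sample library scale, and gene-wise NB dispersions
#' drawn log-uniformly. Counts are NB draws around
#' `profile * library_scale`, so the library scale is identifiable as the
#' sample's mean count, matching the model's scaling convention.
#'
#' Archetypes are placed on scaled coordinate axes (requires
#' `latent_dim >= n_tissues`) so that every pair of tissue centers is
#' exactly `separation` apart.
#'
#' @param n_tissues Number of tissue archetypes T.
#' @param genes Number of genes G.
#' @param samples_per_tissue Samples drawn per tissue.
#' @param latent_dim True latent dimension (>= `n_tissues`).
#' @param separation Euclidean distance between any two tissue archetypes.
#' @param noise_sd Isotropic latent noise around the archetype.
#' @param scale_meanlog,scale_sdlog Log-normal parameters of the per-sample
#'   library scale (mean count per gene).
#' @param dispersion_range Gene-wise NB dispersions are drawn log-uniformly
#'   over this interval.
#' @param seed Optional RNG seed; the same seed reproduces the cohort
#'   exactly.
#' @return List with `counts` (samples x genes integer matrix) and `truth`,
#'   a list holding `tissue`, `latent` (N x D), `archetypes` (T x D),
#'   `profiles` (T x G archetype relative profiles), `sample_profile`
#'   (N x G realized relative profiles), `library_scale`, `dispersion`,
#'   and the truth decoder (`A`, `b`).
#' @examples
#' sim <- simulate_cohort(n_tissues = 2, genes = 30, samples_per_tissue = 5, seed = 1)
#' dim(sim$counts)
#' @export
simulate_cohort <- function(n_tissues = 5, genes = 200, samples_per_tissue = 100,
                            latent_dim = 5, separation = 6, noise_sd = 0.5,
                            scale_meanlog = log(200), scale_sdlog = 0.3,
                            dispersion_range = c(0.5, 20), seed = NULL) {
  if (n_tissues < 1 || genes < 1 || samples_per_tissue < 1)
    stop_dgd("all cohort sizes must be >= 1")
  if (separation <= 0 || noise_sd < 0) stop_dgd("'separation' must be > 0 and 'noise_sd' >= 0")
  if (latent_dim < n_tissues)
    stop_dgd("'latent_dim' must be >= 'n_tissues' for axis-aligned archetypes")
  if (!is.null(seed)) set.seed(seed)

  n <- n_tissues * samples_per_tissue
  tissue <- rep(paste0("tissue", seq_len(n_tissues)), each = samples_per_tissue)
  arch <- matrix(0, n_tissues, latent_dim)
  arch[cbind(seq_len(n_tissues), seq_len(n_tissues))] <- separation / sqrt(2)

  Zt <- arch[rep(seq_len(n_tissues), each = samples_per_tissue), , drop = FALSE] +
    matrix(stats::rnorm(n * latent_dim, sd = noise_sd), n, latent_dim)

  A <- matrix(stats::rnorm(genes * latent_dim), genes, latent_dim) / sqrt(latent_dim)
  b <- rep(1, genes)
  relu_profile <- function(Z) {
    raw <- pmax(Z %*% t(A) + matrix(b, nrow(Z), genes, byrow = TRUE), 0)
    mu <- rowMeans(raw)
    if (any(mu == 0)) stop_dgd("degenerate configuration: a sample has an all-zero profile")
    raw / mu                                  # relative profile, mean 1 per sample
  }
  sample_profile <- relu_profile(Zt)
  profiles <- relu_profile(arch)

  library_scale <- stats::rlnorm(n, scale_meanlog, scale_sdlog)
  dispersion <- exp(stats::runif(genes, log(dispersion_range[1]), log(dispersion_range[2])))

  mu <- sample_profile * library_scale
  counts <- matrix(stats::rnbinom(n * genes,
                                  size = rep(dispersion, each = n),
                                  mu = mu),
                   n, genes)
  dimnames(counts) <- list(paste0("sample", seq_len(n)),
                           paste0("gene", seq_len(genes)))
  dimnames(sample_profile) <- dimnames(counts)
  dimnames(profiles) <- list(paste0("tissue", seq_len(n_tissues)), colnames(counts))
  names(dispersion) <- colnames(counts)

  list(counts = counts,
       truth = list(tissue = tissue, latent = Zt, archetypes = arch,
                    profiles = profiles, sample_profile = sample_profile,
                    library_scale = library_scale, dispersion = dispersion,
                    A = A, b = b, spiked = NULL))
}

#' Spike known fold changes into one sample
#'
#' Builds the positive-control analogue of a tumor: for each spiked gene the
#' count is redrawn from the NB with its true mean multiplied (up) or
#' divided (down) by `fold`; all other genes are left bit-identical.
#'
#' When `genes` is not given, a default panel of `n_genes` is drawn among
#' genes with above-median relative expression and dispersion of at least
#' `min_dispersion` — the regime where a four-fold shift exceeds the NB
#' noise of a single observation, mirroring how marker panels target
#' robustly expressed, low-noise genes (see the methods vignette for the
#' power analysis behind this).
#'
#' @param x Count vector for the sample to perturb.
#' @param truth The `truth` component of a [simulate_cohort()] result.
#' @param which_sample Index (or name) of the sample within the cohort that
#'   `x` came from; supplies its true means.
#' @param genes Indices or names of genes to spike; `NULL` draws the
#'   default panel.
#' @param n_genes Panel size when `genes` is `NULL`.
#' @param fold Fold change (> 0) applied to the true mean.
#' @param up_frac Fraction of spiked genes shifted up (the rest down).
#' @param min_dispersion Eligibility floor for the default panel.
#' @param seed Optional RNG seed.
#' @return List with `counts` (perturbed vector), `genes` (spiked gene
#'   names), `direction` (per spiked gene), and `fold`.
#' @export
spike_sample <- function(x, truth, which_sample, genes = NULL, n_genes = 20, fold = 4,
                         up_frac = 1, min_dispersion = 8, seed = NULL) {
  if (fold <= 0) stop_dgd("'fold' must be positive")
  if (!is.null(seed)) set.seed(seed)
  prof <- truth$sample_profile[which_sample, ]
  scale <- truth$library_scale[which_sample]
  gene_names <- colnames(truth$sample_profile) %||% names(x) %||%
    paste0("gene", seq_along(x))
  if (is.null(colnames(truth$sample_profile))) names(prof) <- gene_names
  if (is.null(genes)) {
    low_noise <- which(truth$dispersion >= min_dispersion)
    if (length(low_noise) < n_genes)
      stop_dgd("fewer than ", n_genes, " genes with dispersion >= ", min_dispersion)
    eligible <- low_noise[prof[low_noise] >= stats::median(prof)]
    if (length(eligible) < n_genes) {
      # too few well-expressed low-noise genes in this draw: fill the
      # panel pool with the most expressed of the remaining low-noise genes
      rest <- setdiff(low_noise, eligible)
      eligible <- c(eligible, rest[order(prof[rest], decreasing = TRUE)
                                   [seq_len(n_genes - length(eligible))]])
    }
    genes <- sample(eligible, n_genes)
  } else if (is.character(genes)) {
    genes <- match(genes, gene_names)
    if (anyNA(genes)) stop_dgd("unknown spike gene name(s)")
  }
  if (length(genes) == 0L) stop_dgd("empty spike gene set")
  n_up <- round(length(genes) * up_frac)
  dir <- rep(c("up", "down"), c(n_up, length(genes) - n_up))
  mult <- ifelse(dir == "up", fold, 1 / fold)
  out <- x
  out[genes] <- stats::rnbinom(length(genes),
                               size = truth$dispersion[genes],
                               mu = prof[genes] * scale * mult)
  list(counts = out, genes = gene_names[genes], direction = dir, fold = fold)
}
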