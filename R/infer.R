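#' Infer the closest representation for unseen samples
#'
#' For each query sample, finds the latent vector that maximizes
#' [sample_log_joint()] with every model parameter frozen — the in-silico
#' ("closest-normal") control for that sample. One candidate is spawned per
#' mixture component, initialized at the component mean and optimized for
#' `search_epochs` Adam steps; the best candidate by the objective is then
#' refined for `refine_epochs` further steps. If refinement ever ends worse
#' than it started (beyond a 1e-6 tolerance), the pre-refinement vector is
#' restored. Samples are independent problems: their order cannot change
#' any result.
#'
#' @param object A trained [dgd] model.
#' @param x Count vector (one sample) or matrix of samples x genes aligned
#'   to `object$genes`.
#' @param search_epochs Optimization steps for every candidate (default 10).
#' @param refine_epochs Additional steps for the selected candidate
#'   (default 50).
#' @param lr Adam learning rate for the representation (default 0.01, the
#'   same optimizer family and rate as in training).
#' @param betas Adam moment coefficients.
#' @param objective `"joint"` (reconstruction + latent mixture density, the
#'   default) or `"reconstruction"` to select and optimize on the NB
#'   likelihood alone.
#' @param scale_method How the query's library scale is estimated:
#'   `"robust"` (default) refines the initial mean-count scale by the
#'   median of count-to-decoded-profile ratios (a median-of-ratios size
#'   factor, insensitive to a minority of truly differential genes, which
#'   would otherwise inflate the scale and mask their own fold changes);
#'   `"mean"` uses the sample's mean count throughout, the convention
#'   used for training samples.
#' @return An object of class `"dgd_representations"`: list with
#'   `representations` (N x D), `component` (hard assignment of each
#'   inferred vector), `objective` (final log joint per sample),
#'   `candidate_objectives` (N x C), `neg_log_prob_mass` (per sample,
#'   \eqn{-\sum_g \log NB(x_g; m_g, r_g)} at the inferred representation)
#'   and `sample_ids`.
#' @export
dgd_infer <- function(object, x, search_epochs = 10, refine_epochs = 50,
                      lr = 0.01, betas = c(0.5, 0.9),
                      objective = c("joint", "reconstruction"),
                      scale_method = c("robust", "mean")) {
  objective <- match.arg(objective)
  scale_method <- match.arg(scale_method)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  counts <- as_count_matrix(x)
  if (ncol(counts) != length(object$genes))
    stop_dgd("query width must equal model gene count; use align_genes()")
  if (search_epochs < 0 || refine_epochs < 0 || lr <= 0)
    stop_dgd("invalid inference configuration")
  n <- nrow(counts)
  C <- object$gmm$C; D <- object$latent_dim
  r <- exp(object$log_r)
  use_latent <- objective == "joint"

  Z <- matrix(NA_real_, n, D)
  comp <- integer(n)
  obj_final <- numeric(n)
  cand_obj <- matrix(NA_real_, n, C)
  nlpm <- numeric(n)
  scales <- numeric(n)

  # objective (to maximize) and gradient for a set of candidate rows
  eval_obj <- function(zc, xrow, s) {
    fwd <- decoder_forward(object$decoder, zc)
    M <- fwd$output * s + object$mean_floor
    ll <- rowSums(nb_log_pmf(matrix(xrow, nrow(zc), length(xrow), byrow = TRUE), M,
                             matrix(r, nrow(zc), length(r), byrow = TRUE)))
    if (use_latent) ll <- ll + gmm_log_density(zc, object$gmm)
    ll
  }
  grad_obj <- function(zc, xrow, s) {
    fwd <- decoder_forward(object$decoder, zc)
    M <- fwd$output * s + object$mean_floor
    xm <- matrix(xrow, nrow(zc), length(xrow), byrow = TRUE)
    rm <- matrix(r, nrow(zc), length(r), byrow = TRUE)
    dY <- nb_dlogpmf_dm(xm, M, rm) * s
    g <- decoder_backward(object$decoder, fwd, dY)$dZ
    if (use_latent) g <- g + gmm_grad_z(zc, object$gmm)
    g
  }
  run_adam <- function(z0, steps, xrow, s) {
    st <- adam_init(z0)
    z <- z0
    for (i in seq_len(steps)) {
      g <- -grad_obj(z, xrow, s)            # minimize the negative
      if (any(!is.finite(g))) stop_dgd("non-finite objective during inference")
      st2 <- adam_step(z, g, st, lr, betas)
      z <- st2$params; st <- st2$state
    }
    z
  }

  for (i in seq_len(n)) {
    xrow <- counts[i, ]
    s <- mean(xrow)
    if (s <= 0) stop_dgd("all-zero sample ", i, " rejected (sample scale undefined)")
    zc <- run_adam(object$gmm$means, search_epochs, xrow, s)
    ov <- eval_obj(zc, xrow, s)
    cand_obj[i, ] <- ov
    best <- which.max(ov)
    z_sel <- zc[best, , drop = FALSE]
    obj_sel <- ov[best]
    z_ref <- run_adam(z_sel, refine_epochs, xrow, s)
    obj_ref <- eval_obj(z_ref, xrow, s)
    if (obj_ref < obj_sel - 1e-6) {          # refinement overshoot: restore
      z_ref <- z_sel
      obj_ref <- obj_sel
    }
    if (scale_method == "robust") {
      s2 <- robust_scale(object, z_ref, xrow, s)
      if (s2 != s) {                         # re-refine at the robust scale
        z2 <- run_adam(z_ref, refine_epochs, xrow, s2)
        o_start <- eval_obj(z_ref, xrow, s2)
        o_end <- eval_obj(z2, xrow, s2)
        if (o_end < o_start - 1e-6) z2 <- z_ref else obj_ref <- o_end
        z_ref <- z2
        s <- s2
      }
    }
    Z[i, ] <- z_ref
    obj_final[i] <- obj_ref
    comp[i] <- assign_component(z_ref, object$gmm)
    m <- drop(decode(object, z_ref, s))
    nlpm[i] <- -sum(nb_log_pmf(xrow, m, r))
    scales[i] <- s
  }

  structure(list(representations = Z, component = comp, objective = obj_final,
                 candidate_objectives = cand_obj, neg_log_prob_mass = nlpm,
                 sample_scale = scales,
                 sample_ids = rownames(counts) %||% paste0("query", seq_len(n)),
                 objective_kind = objective, scale_method = scale_method),
            class = "dgd_representations")
}

# median-of-ratios size factor against the decoded relative profile:
# robust to a minority of differential genes, which inflate the mean
robust_scale <- function(object, z, x, fallback, min_profile = 0.1) {
  y <- drop(decoder_forward(object$decoder, matrix(z, nrow = 1L))$output)
  keep <- y >= min_profile
  if (sum(keep) < 10L) return(fallback)
  s <- stats::median(x[keep] / y[keep])
  if (!is.finite(s) || s <= 0) fallback else s
}

#' Negative log probability mass of samples under the model
#'
#' The model's total \eqn{-\log} probability of a sample's counts — the
#' product of the gene-wise NB probabilities at the inferred
#' representation's decoded means — used to rank in-distribution versus
#' out-of-distribution (e.g. tumor) samples.
#'
#' @param object A trained [dgd] model.
#' @param x Count vector or samples x genes matrix.
#' @param representations Optional matrix of already-inferred latent vectors
#'   (one row per sample); inferred with [dgd_infer()] defaults when absent.
#' @return Numeric vector, one value per sample.
#' @export
neg_log_prob_mass <- function(object, x, representations = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  counts <- as_count_matrix(x)
  if (is.null(representations)) return(dgd_infer(object, counts)$neg_log_prob_mass)
  if (!is.matrix(representations)) representations <- matrix(representations, nrow = 1L)
  r <- exp(object$log_r)
  vapply(seq_len(nrow(counts)), function(i) {
    m <- drop(decode(object, representations[i, ], mean(counts[i, ])))
    -sum(nb_log_pmf(counts[i, ], m, r))
  }, numeric(1))
}

#' @export
print.dgd_representations <- function(x, ...) {
  cat("Inferred representations for", nrow(x$representations), "sample(s)\n")
  cat("  latent dimension:", ncol(x$representations), "\n")
  cat("  component assignments:", paste(utils::head(x$component, 10L), collapse = " "),
      if (length(x$component) > 10L) "...\n" else "\n")
  cat("  objective:", x$objective_kind, "\n")
  invisible(x)
}

#' @export
as.data.frame.dgd_representations <- function(x, ...) {
  Z <- x$representations
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  data.frame(sample_id = x$sample_ids, Z,
             component = x$component,
             neg_log_prob_mass = x$neg_log_prob_mass,
             check.names = FALSE)
}
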