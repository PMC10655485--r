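#' Exact two-tailed negative binomial p-value
#'
#' The single-sample test: the p-value of an observed count \eqn{x} under
#' \eqn{NB(m, r)} is the total probability of all counts no more probable
#' than \eqn{x},
#' \deqn{p = \sum_{k=0}^{K} NB(k; m, r)\, I[NB(k; m, r) \le NB(x; m, r)],}
#' with \eqn{K} the sample's library size. Ties in pmf value are included
#' (non-strict inequality) and the observed count always contributes, so
#' \eqn{p > 0}.
#'
#' The sum is evaluated exactly in O(log K): the NB pmf is unimodal, so the
#' strict super-level set \eqn{\{k : NB(k) > NB(x)\}} is a contiguous run
#' around the mode found by binary search on each flank, and its mass comes
#' from [stats::pnbinom()] CDF differences (upper flank through the upper
#' tail to preserve precision). Tests compare against the literal
#' brute-force summation.
#'
#' @param x Observed count(s), `0 <= x <= K`.
#' @param m Predicted NB mean(s), positive.
#' @param r NB dispersion(s), positive.
#' @param K Library size (scalar or per-observation).
#' @return p-value(s) in (0, 1], vectorized over the arguments.
#' @examples
#' nb_exact_pvalue(0, m = 5, r = 2, K = 500)
#' @export
nb_exact_pvalue <- function(x, m, r, K) {
  n <- max(length(x), length(m), length(r), length(K))
  x <- rep_len(x, n); m <- rep_len(m, n); r <- rep_len(r, n); K <- rep_len(K, n)
  if (!is_count_vector(x) || !is_count_vector(K)) stop_dgd("'x' and 'K' must be non-negative integers")
  if (any(x > K)) stop_dgd("observed count exceeds library size K")
  if (any(m <= 0) || any(r <= 0)) stop_dgd("'m' and 'r' must be positive")
  vapply(seq_len(n), function(i) nb_exact_pvalue_1(x[i], m[i], r[i], K[i]), numeric(1))
}

nb_exact_pvalue_1 <- function(x, m, r, K) {
  lp <- function(k) dnbinom(k, size = r, mu = m, log = TRUE)
  lx <- lp(x)
  mode <- if (r > 1) min(floor(m * (r - 1) / r), K) else 0
  if (lx >= lp(mode)) {                     # x is (tied with) the mode
    p <- stats::pnbinom(K, size = r, mu = m)
    return(clip_pvalue(p, lx))
  }
  # left flank: pmf non-decreasing on [0, mode]; first k with pmf > pmf(x)
  lo <- bsearch_first(0, mode, function(k) lp(k) > lx)
  # right flank: pmf non-increasing on [mode, K]; last k with pmf > pmf(x)
  hi <- bsearch_last(mode, K, function(k) lp(k) > lx)
  p <- stats::pnbinom(lo - 1, size = r, mu = m) +
    max(0, stats::pnbinom(hi, size = r, mu = m, lower.tail = FALSE) -
           stats::pnbinom(K, size = r, mu = m, lower.tail = FALSE))
  clip_pvalue(p, lx)
}

clip_pvalue <- function(p, lx) {
  max(min(p, 1), exp(lx), .Machine$double.xmin)
}

# smallest k in [lo, hi] with pred(k) TRUE; pred monotone FALSE->TRUE
bsearch_first <- function(lo, hi, pred) {
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (pred(mid)) hi <- mid else lo <- mid + 1
  }
  lo
}

# largest k in [lo, hi] with pred(k) TRUE; pred monotone TRUE->FALSE
bsearch_last <- function(lo, hi, pred) {
  while (lo < hi) {
    mid <- ceiling((lo + hi) / 2)
    if (pred(mid)) lo <- mid else hi <- mid - 1
  }
  lo
}

#' Grid approximation of the two-tailed NB p-value
#'
#' Approximates [nb_exact_pvalue()] from pmf evaluations on an evenly
#' spaced integer grid over \eqn{[0, K]} (default \eqn{10^4} points,
#' endpoints included, rounded and de-duplicated). By unimodality, the
#' counts *more* probable than the observation form one contiguous run;
#' the grid brackets its two boundaries, which are then refined to
#' integers by fitting the NB log pmf's own functional form
#' \eqn{\alpha + \beta k + \gamma \log(k+1)} through the bracketing grid
#' nodes (exact when the dispersion is an integer, near-exact otherwise),
#' and the p-value is the complementary CDF mass over \eqn{[0, K]}. The
#' approximation error is the boundary-location error and vanishes
#' rapidly as the grid refines. When the grid covers every integer
#' (`grid_points >= K + 1`) the result is the exact sum; output is clipped
#' to (0, 1] and the observed count always contributes.
#'
#' @inheritParams nb_exact_pvalue
#' @param grid_points Number of grid points (>= 2).
#' @return Approximate p-value(s) in (0, 1].
#' @export
nb_grid_pvalue <- function(x, m, r, K, grid_points = 1e4) {
  if (grid_points < 2) stop_dgd("'grid_points' must be >= 2")
  n <- max(length(x), length(m), length(r), length(K))
  x <- rep_len(x, n); m <- rep_len(m, n); r <- rep_len(r, n); K <- rep_len(K, n)
  if (!is_count_vector(x) || !is_count_vector(K)) stop_dgd("'x' and 'K' must be non-negative integers")
  if (any(x > K)) stop_dgd("observed count exceeds library size K")
  if (any(m <= 0) || any(r <= 0)) stop_dgd("'m' and 'r' must be positive")
  vapply(seq_len(n), function(i) nb_grid_pvalue_1(x[i], m[i], r[i], K[i], grid_points),
         numeric(1))
}

nb_grid_pvalue_1 <- function(x, m, r, K, grid_points) {
  if (grid_points >= K + 1) return(nb_exact_pvalue_1(x, m, r, K))
  h <- K / (grid_points - 1)
  # if the whole distribution fits inside one grid cell, summing that cell
  # exactly costs no more pmf evaluations than the grid itself
  span <- stats::qnbinom(1e-12, size = r, mu = m, lower.tail = FALSE) -
    stats::qnbinom(1e-12, size = r, mu = m)
  if (span <= h) return(nb_exact_pvalue_1(x, m, r, K))
  grid <- unique(round(seq(0, K, length.out = grid_points)))
  lgp <- dnbinom(grid, size = r, mu = m, log = TRUE)
  lx <- dnbinom(x, size = r, mu = m, log = TRUE)
  above <- lgp > lx                       # strict super-level set on the grid
  if (!any(above))                        # nothing beats the observation
    return(clip_pvalue(stats::pnbinom(K, size = r, mu = m), lx))
  i1 <- which(above)[1]
  i2 <- which(above)[sum(above)]
  # left boundary: smallest integer with pmf > pmf(x)
  lo <- if (i1 == 1L) grid[1] else {
    t <- grid_crossing(grid, lgp, i1 - 1L, i1, lx)
    floor(t) + 1
  }
  # right boundary: largest integer with pmf > pmf(x)
  hi <- if (i2 == length(grid)) grid[length(grid)] else {
    t <- grid_crossing(grid, lgp, i2, i2 + 1L, lx)
    ceiling(t) - 1
  }
  p <- stats::pnbinom(lo - 1, size = r, mu = m) +
    max(0, stats::pnbinom(hi, size = r, mu = m, lower.tail = FALSE) -
           stats::pnbinom(K, size = r, mu = m, lower.tail = FALSE))
  clip_pvalue(p, lx)
}

# Locate the integer k in (grid[ia], grid[ib]] where the log pmf crosses lx.
# The NB log pmf is alpha + beta*k + (r-1)-ish * log-gamma structure; fitting
# alpha + beta*k + gamma*log(k+1) through three bracketing nodes reproduces
# it exactly for r = 2 and closely otherwise. Falls back to linear
# interpolation when the fit is degenerate.
grid_crossing <- function(grid, lgp, ia, ib, lx) {
  idx <- if (ib < length(grid)) c(ia, ib, ib + 1L) else c(ia - 1L, ia, ib)
  ks <- grid[idx]; ls <- lgp[idx]
  t_lin <- grid[ia] + (lx - lgp[ia]) / (lgp[ib] - lgp[ia]) * (grid[ib] - grid[ia])
  A <- cbind(1, ks, log(ks + 1))
  cf <- tryCatch(solve(A, ls), error = function(e) NULL)
  if (is.null(cf) || any(!is.finite(cf))) return(t_lin)
  f <- function(k) cf[1] + cf[2] * k + cf[3] * log(k + 1) - lx
  f_a <- f(grid[ia]); f_b <- f(grid[ib])
  if (!is.finite(f_a) || !is.finite(f_b) || f_a * f_b > 0) return(t_lin)
  stats::uniroot(f, c(grid[ia], grid[ib]), tol = 1e-6)$root
}

#' Log2 fold change with a pseudocount
#'
#' `log2((x + c) / (m + c))` comparing an observed count to the model's
#' predicted mean; the pseudocount keeps zero counts finite and shrinks
#' ratios at low expression.
#'
#' @param x Observed count(s).
#' @param m Predicted mean(s).
#' @param pseudocount Added to both numerator and denominator (default 1).
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(x, m, pseudocount = 1) {
  if (any(x < 0) || any(m <= 0)) stop_dgd("'x' must be >= 0 and 'm' > 0")
  log2((x + pseudocount) / (m + pseudocount))
}

#' Marker-gene enrichment score
#'
#' Ratio of the marker fraction among significant genes to the marker
#' fraction in the whole gene universe:
#' \deqn{ES = \frac{|significant \cap markers| \cdot total}
#'   {|significant| \cdot |markers|}.}
#' 1 means no enrichment; an empty significant or marker set makes the
#' score undefined and returns `NA` (not 0) with a warning.
#'
#' @param significant Character vector (or set) of significant gene IDs.
#' @param markers Character vector of marker gene IDs.
#' @param total_genes Size of the gene universe.
#' @return Non-negative scalar, or `NA_real_` when undefined.
#' @examples
#' enrichment_score(paste0("g", 1:20), paste0("g", c(1:5, 100:144)), 1000) # 5
#' @export
enrichment_score <- function(significant, markers, total_genes) {
  significant <- unique(significant); markers <- unique(markers)
  if (length(significant) == 0L || length(markers) == 0L) {
    warning("enrichment score undefined for empty significant or marker set")
    return(NA_real_)
  }
  if (total_genes < max(length(significant), length(markers)))
    stop_dgd("'total_genes' smaller than the provided sets")
  length(intersect(significant, markers)) * total_genes /
    (length(significant) * length(markers))
}

#' Single-sample differential expression against the model
#'
#' The control-free ("N-of-one") test: each gene's observed count is
#' compared to the negative binomial distribution the model emits at the
#' sample's closest-normal representation. Genes are called differentially
#' expressed when the adjusted p-value falls below `alpha` and the absolute
#' log2 fold change exceeds `lfc`.
#'
#' @param object A trained [dgd] model.
#' @param x Count vector for one sample, aligned to `object$genes`.
#' @param representation Optional pre-inferred latent vector; when absent
#'   the closest-normal representation is inferred with [dgd_infer()]
#'   defaults.
#' @param sample_scale Library scale used to decode the reference means;
#'   defaults to the scale estimated during inference (median-of-ratios;
#'   see [dgd_infer()]). Pass `mean(x)` to force the plain mean-count
#'   convention.
#' @param pvalue `"exact"` for the full sum or `"grid"` for the
#'   grid approximation.
#' @param grid_points Grid size for `pvalue = "grid"`.
#' @param alpha Adjusted p-value threshold (default 0.01).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param adjust Multiple-testing adjustment, `"BH"` (default) or
#'   `"bonferroni"`, applied via [stats::p.adjust()].
#' @param pseudocount Pseudocount for [log2_fold_change()].
#' @param ... Passed to [dgd_infer()] when the representation is inferred
#'   here (e.g. `lr`).
#' @return A data frame of class `"dgd_de"` with one row per gene:
#'   `gene_id`, `observed`, `predicted_mean`, `dispersion`, `pvalue`,
#'   `padj`, `log2fc`, `called`, `direction`; thresholds, the library size
#'   and the representation are kept as attributes.
#' @export
dgd_test <- function(object, x, representation = NULL, sample_scale = NULL,
                     pvalue = c("exact", "grid"), grid_points = 1e4,
                     alpha = 0.01, lfc = 1, adjust = c("BH", "bonferroni"),
                     pseudocount = 1, ...) {
  pvalue <- match.arg(pvalue)
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop_dgd("'alpha' must be in (0, 1)")
  if (!is.null(dim(x))) {
    if (nrow(x) != 1L) stop_dgd("'x' must be a single sample")
    x <- drop(as.matrix(x))
  }
  if (length(x) != length(object$genes)) stop_dgd("'x' must be aligned to model genes")
  if (!is_count_vector(x)) stop_dgd("counts must be non-negative integers")
  if (is.null(representation)) {
    inf <- dgd_infer(object, x, ...)
    representation <- drop(inf$representations)
    sample_scale <- sample_scale %||% inf$sample_scale
  }
  sample_scale <- sample_scale %||%
    robust_scale(object, representation, x, mean(x))
  K <- sum(x)
  m <- drop(decode(object, representation, sample_scale))
  r <- exp(object$log_r)
  p <- switch(pvalue,
              exact = nb_exact_pvalue(x, m, r, K),
              grid = nb_grid_pvalue(x, m, r, K, grid_points))
  padj <- stats::p.adjust(p, method = if (adjust == "BH") "BH" else "bonferroni")
  l2fc <- log2_fold_change(x, m, pseudocount)
  called <- padj < alpha & abs(l2fc) > lfc
  res <- data.frame(gene_id = object$genes, observed = as.integer(round(x)),
                    predicted_mean = m, dispersion = r,
                    pvalue = p, padj = padj, log2fc = l2fc, called = called,
                    direction = ifelse(l2fc > 0, "up", ifelse(l2fc < 0, "down", "none")),
                    row.names = NULL)
  attr(res, "alpha") <- alpha
  attr(res, "lfc") <- lfc
  attr(res, "library_size") <- K
  attr(res, "pvalue_mode") <- pvalue
  attr(res, "representation") <- representation
  class(res) <- c("dgd_de", "data.frame")
  res
}

#' @export
print.dgd_de <- function(x, ...) {
  cat("Single-sample differential expression (", attr(x, "pvalue_mode"),
      " NB test)\n", sep = "")
  cat("  genes tested: ", nrow(x), "   library size K = ",
      attr(x, "library_size"), "\n", sep = "")
  cat("  called: ", sum(x$called), " (padj < ", attr(x, "alpha"),
      ", |log2FC| > ", attr(x, "lfc"), "); up ",
      sum(x$called & x$direction == "up"), ", down ",
      sum(x$called & x$direction == "down"), "\n", sep = "")
  called <- x[x$called, c("gene_id", "observed", "predicted_mean", "padj", "log2fc")]
  if (nrow(called)) print(utils::head(called[order(called$padj), ], 10L))
  invisible(x)
}
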