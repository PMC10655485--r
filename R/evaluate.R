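#' Matrix of associations between tissues and mixture components
#'
#' For each non-empty mixture component, the percentage of its samples
#' contributed by every tissue:
#' \deqn{entry(t, c) = 100 \cdot \frac{\#\{\text{samples of tissue } t
#'   \text{ in component } c\}}{\#\{\text{samples in component } c\}}.}
#' Columns therefore sum to 100. Components with no assigned samples are
#' omitted (there is nothing to normalize). Also derives the
#' component-to-majority-tissue map used by [tissue_match_percentage()];
#' majority ties break toward the tissue with the larger overall cohort.
#'
#' @param components Integer component assignment per sample (e.g. from
#'   [assign_component()] or [dgd_infer()]).
#' @param tissues Tissue label per sample.
#' @return An object of class `"dgd_association"`: list with `percent`
#'   (tissues x components), `component_n`, `tissue_n`, and `majority`
#'   (named character vector, component index -> majority tissue).
#' @export
association_matrix <- function(components, tissues) {
  if (length(components) != length(tissues))
    stop_dgd("'components' and 'tissues' must have equal length")
  tissues <- as.character(tissues)
  components <- as.integer(components)
  tab <- table(tissue = tissues, component = components)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  comp_n <- colSums(counts)
  percent <- sweep(counts, 2L, comp_n, `/`) * 100
  tissue_n <- table(tissues)
  majority <- apply(counts, 2L, function(col) {
    best <- which(col == max(col))
    if (length(best) > 1L)                      # tie: larger tissue cohort wins
      best <- best[which.max(tissue_n[rownames(counts)[best]])]
    rownames(counts)[best]
  })
  structure(list(percent = percent, component_n = comp_n,
                 tissue_n = c(tissue_n), majority = majority),
            class = "dgd_association")
}

#' @export
print.dgd_association <- function(x, digits = 1, ...) {
  cat("Matrix of associations (% of component samples per tissue)\n")
  print(round(x$percent, digits))
  cat("samples per component:\n")
  print(x$component_n)
  invisible(x)
}

#' Percentage of query samples matched to their tissue's components
#'
#' For every query tissue, the percentage of its samples whose assigned
#' mixture component has that tissue as its majority in the training
#' association matrix. A tissue represented by several majority components
#' counts a match to any of them; a tissue that is no component's majority
#' scores 0 (unmatched, not an error).
#'
#' @param components Component assignment per query sample.
#' @param tissues Tissue label per query sample.
#' @param majority Component-to-tissue majority map: a
#'   [association_matrix()] result or its `majority` named vector.
#' @return Named numeric vector of percentages, one per query tissue.
#' @export
tissue_match_percentage <- function(components, tissues, majority) {
  if (inherits(majority, "dgd_association")) majority <- majority$majority
  if (length(components) != length(tissues))
    stop_dgd("'components' and 'tissues' must have equal length")
  tissues <- as.character(tissues)
  mapped <- unname(majority[as.character(components)])   # NA if unseen component
  matched <- !is.na(mapped) & mapped == tissues
  out <- vapply(sort(unique(tissues)), function(t) {
    sel <- tissues == t
    100 * sum(matched[sel]) / sum(sel)
  }, numeric(1))
  out
}
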